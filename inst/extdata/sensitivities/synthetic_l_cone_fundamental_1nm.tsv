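# synthetic L sensitivity: Govardovskii A1 nomogram, corneal peak 565 nm, peak-normalized
wavelength_nm	value
380	0.254158219
381	0.252962785
382	0.2516836071
383	0.2503229794
384	0.24888332
385	0.2473671674
386	0.2457771775
387	0.2441161202
388	0.2423868754
389	0.2405924299
390	0.2387358731
391	0.2368203932
392	0.2348492732
393	0.2328258865
394	0.230753693
395	0.2286362347
396	0.2264771312
397	0.2242800754
398	0.2220488292
399	0.219787219
400	0.2174991312
401	0.2151885076
402	0.2128593414
403	0.2105156723
404	0.2081615827
405	0.2058011928
406	0.2034386566
407	0.2010781578
408	0.1987239053
409	0.1963801295
410	0.1940510783
411	0.1917410129
412	0.1894542041
413	0.1871949289
414	0.1849674665
415	0.1827760952
416	0.1806250887
417	0.1785187129
418	0.1764612228
419	0.1744568596
420	0.1725098475
421	0.170624391
422	0.1688046721
423	0.167054848
424	0.1653790481
425	0.163781372
426	0.162265887
427	0.1608366259
428	0.1594975848
429	0.158252721
430	0.1571059512
431	0.1560611493
432	0.1551221444
433	0.1542927193
434	0.1535766082
435	0.1529774953
436	0.1524990125
437	0.1521447382
438	0.1519181947
439	0.1518228468
440	0.1518621
441	0.1520392981
442	0.1523577216
443	0.1528205852
444	0.1534310362
445	0.1541921516
446	0.1551069363
447	0.1561783202
448	0.1574091561
449	0.1588022165
450	0.1603601911
451	0.1620856835
452	0.1639812086
453	0.1660491889
454	0.1682919512
455	0.1707117231
456	0.1733106294
457	0.1760906879
458	0.1790538059
459	0.1822017754
460	0.1855362697
461	0.1890588382
462	0.1927709022
463	0.1966737504
464	0.2007685341
465	0.2050562624
466	0.209537797
467	0.2142138482
468	0.219084969
469	0.2241515508
470	0.2294138182
471	0.2348718242
472	0.2405254456
473	0.2463743779
474	0.2524181311
475	0.2586560251
476	0.2650871852
477	0.2717105386
478	0.2785248099
479	0.285528518
480	0.2927199727
481	0.3000972715
482	0.3076582971
483	0.3154007152
484	0.3233219724
485	0.331419295
486	0.3396896874
487	0.3481299321
488	0.3567365891
489	0.3655059963
490	0.3744342703
491	0.3835173076
492	0.3927507865
493	0.4021301691
494	0.4116507044
495	0.4213074309
496	0.4310951809
497	0.4410085842
498	0.4510420729
499	0.461189886
500	0.4714460753
501	0.4818045106
502	0.4922588861
503	0.5028027265
504	0.5134293938
505	0.524132094
506	0.5349038842
507	0.5457376796
508	0.5566262609
509	0.5675622815
510	0.578538275
511	0.5895466622
512	0.6005797586
513	0.6116297811
514	0.6226888552
515	0.6337490219
516	0.6448022437
517	0.6558404109
518	0.6668553479
519	0.6778388182
520	0.6887825302
521	0.6996781412
522	0.7105172626
523	0.7212914635
524	0.7319922743
525	0.7426111898
526	0.7531396723
527	0.7635691535
528	0.7738910368
529	0.7840966986
530	0.7941774898
531	0.8041247366
532	0.8139297414
533	0.8235837829
534	0.8330781167
535	0.8424039757
536	0.8515525698
537	0.8605150863
538	0.8692826906
539	0.8778465263
540	0.886197716
541	0.8943273628
542	0.9022265518
543	0.9098863523
544	0.9172978207
545	0.9244520044
546	0.931339946
547	0.9379526892
548	0.9442812855
549	0.9503168017
550	0.9560503294
551	0.9614729956
552	0.9665759747
553	0.9713505021
554	0.9757878896
555	0.9798795427
556	0.9836169792
557	0.9869918497
558	0.9899959608
559	0.9926212988
560	0.9948600564
561	0.9967046606
562	0.9981478024
563	0.9991824686
564	0.9998019749
565	1
566	0.9997706218
567	0.9991083541
568	0.9980081844
569	0.9964656122
570	0.9944766878
571	0.9920380506
572	0.9891469681
573	0.9858013728
574	0.9819998998
575	0.977741921
576	0.9730275793
577	0.9678578191
578	0.9622344151
579	0.9561599972
580	0.9496380728
581	0.9426730442
582	0.9352702228
583	0.9274358377
584	0.9191770401
585	0.9105019025
586	0.9014194122
587	0.8919394596
588	0.882072821
589	0.8718311354
590	0.8612268761
591	0.8502733166
592	0.8389844917
593	0.8273751525
594	0.8154607179
595	0.803257221
596	0.7907812514
597	0.7780498949
598	0.7650806693
599	0.7518914583
600	0.7385004438
601	0.7249260363
602	0.7111868056
603	0.6973014109
604	0.683288532
605	0.6691668015
606	0.654954739
607	0.6406706873
608	0.6263327523
609	0.6119587451
610	0.5975661287
611	0.5831719683
612	0.5687928857
613	0.5544450192
614	0.5401439866
615	0.5259048545
616	0.5117421117
617	0.4976696468
618	0.4837007318
619	0.4698480092
620	0.4561234834
621	0.4425385174
622	0.4291038317
623	0.4158295084
624	0.4027249971
625	0.389799125
626	0.3770601083
627	0.364515567
628	0.3521725408
629	0.3400375063
630	0.328116396
631	0.3164146173
632	0.3049370724
633	0.293688178
634	0.2826718848
635	0.2718916971
636	0.2613506903
637	0.2510515293
638	0.2409964842
639	0.2311874457
640	0.2216259392
641	0.2123131368
642	0.2032498687
643	0.1944366327
644	0.1858736029
645	0.1775606365
646	0.1694972804
647	0.1616827759
648	0.1541160634
649	0.1467957862
650	0.139720294
651	0.1328876466
652	0.126295617
653	0.1199416955
654	0.1138230944
655	0.1079367528
656	0.1022793431
657	0.09684727786
658	0.09163671874
659	0.08664358584
660	0.08186356902
661	0.07729214042
662	0.07292456824
663	0.06875593199
664	0.06478113884
665	0.0609949411
666	0.05739195467
667	0.05396667824
668	0.05071351309
669	0.0476267833
670	0.04470075606
671	0.0419296621
672	0.03930771571
673	0.03682913449
674	0.03448815838
675	0.03227906791
676	0.03019620162
677	0.02823397222
678	0.02638688178
679	0.02464953552
680	0.02301665431
681	0.02148308584
682	0.02004381438
683	0.01869396916
684	0.0174288314
685	0.01624383998
686	0.01513459589
687	0.01409686545
688	0.01312658232
689	0.01221984855
690	0.01137293457
691	0.01058227832
692	0.009844483556
693	0.009156317469
694	0.008514707621
695	0.007916738383
696	0.007359646888
697	0.006840818592
698	0.00635778253
699	0.005908206318
700	0.005489890969
701	0.005100765581
702	0.004738881946
703	0.004402409126
704	0.004089628033
705	0.003798926057
706	0.003528791762
707	0.003277809681
708	0.003044655236
709	0.002828089793
710	0.002626955868
711	0.002440172502
712	0.00226673081
713	0.0021056897
714	0.001956171786
715	0.001817359477
716	0.001688491256
717	0.001568858142
718	0.001457800328
719	0.001354704002
720	0.001258998342
721	0.001170152671
722	0.001087673787
723	0.001011103436
724	0.0009400159516
725	0.000874016021
726	0.0008127366038
727	0.0007558369737
728	0.0007030008874
729	0.000653934872
730	0.0006083666232
731	0.0005660435103
732	0.0005267311807
733	0.0004902122584
734	0.0004562851305
735	0.0004247628174
736	0.0003954719209
737	0.0003682516444
738	0.0003429528832
739	0.0003194373771
740	0.0002975769235
741	0.0002772526469
742	0.0002583543195
743	0.0002407797309
744	0.0002244341031
745	0.0002092295475
746	0.0001950845615
747	0.000181923561
748	0.0001696764471
749	0.0001582782051
750	0.0001476685312
751	0.0001377914884
752	0.0001285951857
753	0.0001200314824
754	0.0001120557132
755	0.0001046264337
756	9.770518466e-05
757	9.125627393e-05
758	8.52465738e-05
759	7.964533378e-05
760	7.442400704e-05
761	6.955608961e-05
762	6.501697148e-05
763	6.078379867e-05
764	5.683534546e-05
765	5.315189605e-05
766	4.971513494e-05
767	4.650804537e-05
768	4.351481526e-05
769	4.072075004e-05
770	3.811219192e-05
771	3.567644509e-05
772	3.340170638e-05
773	3.127700105e-05
774	2.929212325e-05
775	2.743758086e-05
776	2.570454436e-05
777	2.408479942e-05
778	2.257070301e-05
779	2.115514262e-05
780	1.98314985e-05
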