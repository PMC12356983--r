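# synthetic M sensitivity: Govardovskii A1 nomogram, corneal peak 535 nm, peak-normalized
wavelength_nm	value
380	0.2401724656
381	0.2382005379
382	0.2361774749
383	0.2341081159
384	0.2319974159
385	0.2298504387
386	0.2276723497
387	0.225468409
388	0.2232439635
389	0.2210044402
390	0.2187553389
391	0.2165022244
392	0.21425072
393	0.2120064998
394	0.2097752815
395	0.2075628199
396	0.2053748992
397	0.2032173267
398	0.2010959255
399	0.1990165283
400	0.1969849707
401	0.1950070845
402	0.1930886918
403	0.1912355986
404	0.1894535891
405	0.1877484192
406	0.1861258116
407	0.1845914494
408	0.1831509712
409	0.1818099656
410	0.1805739658
411	0.1794484446
412	0.1784388098
413	0.1775503984
414	0.1767884729
415	0.1761582155
416	0.1756647243
417	0.1753130083
418	0.1751079825
419	0.1750544641
420	0.1751571674
421	0.1754206996
422	0.1758495557
423	0.1764481149
424	0.1772206349
425	0.1781712483
426	0.1793039569
427	0.1806226277
428	0.1821309876
429	0.1838326188
430	0.1857309534
431	0.1878292684
432	0.1901306807
433	0.1926381415
434	0.1953544311
435	0.198282153
436	0.2014237288
437	0.2047813923
438	0.2083571835
439	0.2121529433
440	0.2161703071
441	0.2204106993
442	0.2248753273
443	0.2295651758
444	0.2344810006
445	0.2396233232
446	0.2449924251
447	0.2505883422
448	0.2564108593
449	0.2624595056
450	0.2687335488
451	0.2752319914
452	0.2819535657
453	0.2888967302
454	0.2960596658
455	0.3034402726
456	0.3110361671
457	0.3188446804
458	0.3268628556
459	0.3350874474
460	0.343514921
461	0.3521414523
462	0.3609629283
463	0.3699749483
464	0.3791728262
465	0.3885515922
466	0.3981059968
467	0.4078305141
468	0.4177193462
469	0.4277664288
470	0.4379654364
471	0.4483097889
472	0.4587926583
473	0.4694069762
474	0.4801454416
475	0.4910005293
476	0.5019644988
477	0.5130294031
478	0.5241870981
479	0.5354292528
480	0.5467473582
481	0.5581327381
482	0.5695765585
483	0.5810698378
484	0.5926034566
485	0.6041681678
486	0.6157546056
487	0.6273532952
488	0.6389546619
489	0.650549039
490	0.662126677
491	0.6736777505
492	0.6851923656
493	0.6966605672
494	0.7080723441
495	0.7194176354
496	0.7306863348
497	0.7418682957
498	0.7529533341
499	0.7639312323
500	0.7747917414
501	0.7855245836
502	0.7961194532
503	0.8065660186
504	0.8168539226
505	0.826972783
506	0.8369121931
507	0.8466617217
508	0.8562109133
509	0.8655492886
510	0.8746663445
511	0.8835515553
512	0.8921943737
513	0.9005842328
514	0.9087105483
515	0.9165627226
516	0.9241301488
517	0.9314022164
518	0.9383683189
519	0.9450178617
520	0.951340273
521	0.9573250152
522	0.9629615997
523	0.9682396024
524	0.9731486824
525	0.9776786026
526	0.9818192529
527	0.9855606757
528	0.9888930943
529	0.9918069433
530	0.9942929024
531	0.9963419319
532	0.9979453112
533	0.9990946797
534	0.9997820794
535	1
536	0.9997414259
537	0.9989998842
538	0.9977694943
539	0.996045018
540	0.9938219106
541	0.9910963713
542	0.9878653934
543	0.9841268131
544	0.9798793576
545	0.9751226894
546	0.9698574496
547	0.9640852961
548	0.957808939
549	0.9510321708
550	0.9437598915
551	0.9359981278
552	0.9277540465
553	0.9190359608
554	0.9098533293
555	0.9002167485
556	0.890137937
557	0.8796297117
558	0.8687059573
559	0.8573815872
560	0.8456724969
561	0.833595511
562	0.8211683223
563	0.8084094252
564	0.7953380432
565	0.7819740512
566	0.7683378931
567	0.7544504966
568	0.7403331846
569	0.7260075849
570	0.7114955387
571	0.6968190101
572	0.6819999949
573	0.667060432
574	0.6520221179
575	0.636906623
576	0.6217352132
577	0.6065287761
578	0.5913077515
579	0.5760920686
580	0.5609010886
581	0.5457535545
582	0.5306675459
583	0.5156604422
584	0.5007488912
585	0.4859487845
586	0.4712752392
587	0.456742586
588	0.4423643629
589	0.4281533135
590	0.4141213916
591	0.4002797694
592	0.3866388496
593	0.3732082815
594	0.3599969794
595	0.3470131439
596	0.3342642849
597	0.3217572451
598	0.3094982258
599	0.2974928116
600	0.2857459957
601	0.2742622044
602	0.2630453207
603	0.2520987071
604	0.2414252262
605	0.2310272601
606	0.2209067279
607	0.2110651015
608	0.201503419
609	0.192222297
610	0.1832219403
611	0.1745021509
612	0.1660623347
613	0.157901508
614	0.1500183025
615	0.1424109698
616	0.1350773863
617	0.1280150578
618	0.1212211241
619	0.1146923657
620	0.1084252101
621	0.1024157408
622	0.09665970677
623	0.09115253479
624	0.08588934262
625	0.0808649549
626	0.07607392068
627	0.07151053298
628	0.06716885013
629	0.06304271876
630	0.05912579829
631	0.05541158656
632	0.05189344646
633	0.04856463313
634	0.04541832155
635	0.04244763404
636	0.0396456676
637	0.03700552047
638	0.03452031795
639	0.032183237
640	0.02998752949
641	0.02792654393
642	0.02599374545
643	0.02418273394
644	0.02248726032
645	0.02090124083
646	0.01941876934
647	0.01803412769
648	0.01674179417
649	0.01553645007
650	0.01441298455
651	0.0133664978
652	0.01239230269
653	0.01148592497
654	0.01064310225
655	0.009859781724
656	0.009132117002
657	0.008456463939
658	0.00782937577
659	0.00724759759
660	0.006708060298
661	0.006207874136
662	0.005744321901
663	0.005314851929
664	0.004917070926
665	0.004548736729
666	0.004207751049
667	0.003892152256
668	0.003600108262
669	0.003329909526
670	0.003079962228
671	0.002848781642
672	0.002634985714
673	0.002437288881
674	0.002254496129
675	0.002085497313
676	0.001929261725
677	0.001784832934
678	0.001651323882
679	0.001527912238
680	0.001413836008
681	0.001308389394
682	0.001210918892
683	0.001120819628
684	0.001037531915
685	0.000960538027
686	0.000889359179
687	0.0008235527064
688	0.0007627094277
689	0.0007064511864
690	0.0006544285601
691	0.0006063187273
692	0.0005618234834
693	0.000520667397
694	0.0004825960964
695	0.0004473746808
696	0.0004147862452
697	0.0003846305135
698	0.0003567225723
699	0.0003308916979
700	0.0003069802707
701	0.0002848427708
702	0.0002643448489
703	0.0002453624673
704	0.0002277811063
705	0.0002114950304
706	0.0001964066106
707	0.0001824256991
708	0.0001694690511
709	0.0001574597915
710	0.0001463269225
711	0.0001360048699
712	0.0001264330629
713	0.0001175555484
714	0.0001093206335
715	0.0001016805568
716	9.45911849e-05
717	8.801173211e-05
718	8.190450263e-05
719	7.623465229e-05
720	7.096996903e-05
721	6.608067041e-05
722	6.153921685e-05
723	5.732013945e-05
724	5.339988115e-05
725	4.975665033e-05
726	4.637028565e-05
727	4.322213153e-05
728	4.029492318e-05
729	3.757268064e-05
730	3.504061099e-05
731	3.268501811e-05
732	3.049321949e-05
733	2.845346941e-05
734	2.655488806e-05
735	2.47873962e-05
736	2.314165471e-05
737	2.160900896e-05
738	2.018143732e-05
739	1.88515037e-05
740	1.761231368e-05
741	1.645747407e-05
742	1.538105543e-05
743	1.437755762e-05
744	1.344187783e-05
745	1.25692811e-05
746	1.175537311e-05
747	1.099607499e-05
748	1.028760002e-05
749	9.626432156e-06
750	9.009306134e-06
751	8.433189063e-06
752	7.895263426e-06
753	7.392911354e-06
754	6.923700064e-06
755	6.485368403e-06
756	6.075814384e-06
757	5.693083653e-06
758	5.335358823e-06
759	5.000949584e-06
760	4.68828356e-06
761	4.395897834e-06
762	4.122431102e-06
763	3.866616401e-06
764	3.627274377e-06
765	3.40330704e-06
766	3.193691987e-06
767	2.997477033e-06
768	2.813775246e-06
769	2.641760336e-06
770	2.480662382e-06
771	2.329763868e-06
772	2.188396006e-06
773	2.055935321e-06
774	1.931800491e-06
775	1.815449402e-06
776	1.706376426e-06
777	1.604109884e-06
778	1.508209698e-06
779	1.418265205e-06
780	1.333893129e-06
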