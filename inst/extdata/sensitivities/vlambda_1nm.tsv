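# V(lambda): CIE 1931 ybar 10-nm table spline-interpolated to 1 nm, peak-normalized
wavelength_nm	value
400	0.0003999375743
401	0.0004548315934
402	0.0005112464303
403	0.0005707029032
404	0.0006347218298
405	0.0007048240281
406	0.0007825303161
407	0.0008693615116
408	0.0009668384326
409	0.001076481897
410	0.001199812723
411	0.001338830598
412	0.00149745069
413	0.001680067036
414	0.001891073675
415	0.002134864643
416	0.002415833978
417	0.002738375718
418	0.0031068839
419	0.003525752563
420	0.003999375743
421	0.004531031874
422	0.005119536969
423	0.00576259144
424	0.006457895695
425	0.007203150144
426	0.007996055198
427	0.008834311267
428	0.009715618759
429	0.01063767808
430	0.01159818965
431	0.01259503802
432	0.0136268443
433	0.01469241375
434	0.01579055163
435	0.0169200632
436	0.01807975373
437	0.01926842846
438	0.02048489267
439	0.0217279516
440	0.02299641052
441	0.02429025361
442	0.02561418068
443	0.02697407048
444	0.02837580174
445	0.02982525321
446	0.03132830363
447	0.03289083173
448	0.03451871626
449	0.03621783596
450	0.03799406956
451	0.03985199545
452	0.04179099058
453	0.04380913155
454	0.04590449496
455	0.04807515741
456	0.05031919549
457	0.05263468581
458	0.05501970496
459	0.05747232954
460	0.05999063615
461	0.06257532411
462	0.0652375837
463	0.06799122791
464	0.07085006973
465	0.07382792215
466	0.07693859817
467	0.08019591079
468	0.083613673
469	0.08720569779
470	0.09098579815
471	0.09496459558
472	0.09913994552
473	0.1035065119
474	0.1080589586
475	0.1127919497
476	0.117700149
477	0.1227782204
478	0.128020828
479	0.1334226355
480	0.1389783071
481	0.1446886504
482	0.1505790492
483	0.156681031
484	0.1630261232
485	0.1696458535
486	0.1765717493
487	0.1838353382
488	0.1914681477
489	0.1995017053
490	0.2079675386
491	0.2168967877
492	0.2263190424
493	0.2362635054
494	0.2467593793
495	0.2578358665
496	0.2695221695
497	0.281847491
498	0.2948410334
499	0.3085319993
500	0.3229495912
501	0.3381124187
502	0.3539967193
503	0.3705681375
504	0.3877923179
505	0.405634905
506	0.4240615433
507	0.4430378774
508	0.4625295518
509	0.482502211
510	0.5029214997
511	0.5237388306
512	0.5448486904
513	0.5661313339
514	0.5874670161
515	0.6087359917
516	0.6298185158
517	0.6505948432
518	0.6709452288
519	0.6907499276
520	0.7098891944
521	0.7282668104
522	0.745880662
523	0.7627521618
524	0.7789027224
525	0.7943537566
526	0.8091266769
527	0.823242896
528	0.8367238266
529	0.8495908812
530	0.8618654726
531	0.8735661278
532	0.8846998316
533	0.8952706832
534	0.9052827817
535	0.9147402264
536	0.9236471165
537	0.9320075512
538	0.9398256297
539	0.9471054511
540	0.9538511147
541	0.9600687335
542	0.9657724759
543	0.9709785238
544	0.9757030596
545	0.9799622652
546	0.9837723228
547	0.9871494146
548	0.9901097226
549	0.9926694291
550	0.9948447161
551	0.9966475958
552	0.9980734012
553	0.9991132951
554	0.9997584403
555	1
556	0.9998291369
557	0.9992370141
558	0.9982147944
559	0.9967536407
560	0.9948447161
561	0.9924818509
562	0.9896695456
563	0.9864149683
564	0.9827252871
565	0.97860767
566	0.9740692849
567	0.9691173001
568	0.9637588834
569	0.958001203
570	0.9518514268
571	0.9453162219
572	0.9384002504
573	0.9311076736
574	0.9234426525
575	0.9154093485
576	0.9070119227
577	0.8982545361
578	0.8891413501
579	0.8796765257
580	0.8698642241
581	0.859711943
582	0.8492405256
583	0.8384741519
584	0.8274370015
585	0.8161532543
586	0.8046470902
587	0.7929426888
588	0.78106423
589	0.7690358936
590	0.7568818594
591	0.744623461
592	0.7322706474
593	0.7198305213
594	0.7073101855
595	0.6947167429
596	0.6820572961
597	0.669338948
598	0.6565688014
599	0.6437539589
600	0.6309015235
601	0.6180196471
602	0.6051206793
603	0.5922180189
604	0.5793250646
605	0.5664552152
606	0.5536218696
607	0.5408384264
608	0.5281182845
609	0.5154748427
610	0.5029214997
611	0.4904673036
612	0.4781038998
613	0.4658185828
614	0.4535986472
615	0.4414313876
616	0.4293040985
617	0.4172040746
618	0.4051186104
619	0.3930350005
620	0.3809405395
621	0.3688308768
622	0.3567350803
623	0.3446905732
624	0.3327347781
625	0.320905118
626	0.3092390158
627	0.2977738943
628	0.2865471764
629	0.275596285
630	0.264958643
631	0.2546626019
632	0.2447002282
633	0.2350545171
634	0.2257084638
635	0.2166450635
636	0.2078473114
637	0.1992982027
638	0.1909807326
639	0.1828778962
640	0.1749726888
641	0.1672520396
642	0.1597186148
643	0.1523790142
644	0.1452398382
645	0.1383076867
646	0.1315891598
647	0.1250908578
648	0.1188193805
649	0.1127813283
650	0.1069833011
651	0.1014292332
652	0.09611239478
653	0.09102339037
654	0.08615282432
655	0.08149130104
656	0.07702942492
657	0.07275780037
658	0.06866703178
659	0.06474772355
660	0.06099048008
661	0.0573876362
662	0.05393844847
663	0.05064390386
664	0.04750498937
665	0.04452269197
666	0.04169799866
667	0.03903189642
668	0.03652537223
669	0.03417941307
670	0.03199500594
671	0.02997088174
672	0.02809674701
673	0.02636005223
674	0.02474824787
675	0.0232487844
676	0.02184911229
677	0.02053668202
678	0.01929894405
679	0.01812334886
680	0.01699734691
681	0.01591088334
682	0.01486388192
683	0.01385876109
684	0.01289793928
685	0.01198383493
686	0.01111886647
687	0.01030545235
688	0.009546010978
689	0.008842960809
690	0.008198720273
691	0.007614284265
692	0.007084953519
693	0.006604605226
694	0.006167116582
695	0.005766364779
696	0.005396227009
697	0.005050580467
698	0.004723302346
699	0.004408269838
700	0.004099360137
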