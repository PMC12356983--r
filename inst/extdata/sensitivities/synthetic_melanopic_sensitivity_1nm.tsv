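# synthetic Mel sensitivity: Govardovskii A1 nomogram, corneal peak 490 nm, peak-normalized
wavelength_nm	value
380	0.2271702124
381	0.2261238704
382	0.2251949963
383	0.2243927871
384	0.2237263302
385	0.2232045859
386	0.2228363713
387	0.2226303435
388	0.2225949833
389	0.2227385799
390	0.2230692146
391	0.2235947458
392	0.224322794
393	0.2252607266
394	0.2264156442
395	0.2277943657
396	0.2294034148
397	0.2312490063
398	0.233337033
399	0.2356730528
400	0.2382622758
401	0.2411095525
402	0.2442193619
403	0.2475957995
404	0.251242567
405	0.2551629613
406	0.2593598642
407	0.2638357329
408	0.2685925912
409	0.2736320203
410	0.2789551513
411	0.2845626578
412	0.2904547492
413	0.2966311648
414	0.3030911691
415	0.309833547
416	0.3168566007
417	0.3241581473
418	0.3317355172
419	0.3395855537
420	0.3477046133
421	0.3560885678
422	0.3647328063
423	0.3736322399
424	0.382781306
425	0.3921739747
426	0.4018037558
427	0.4116637076
428	0.4217464458
429	0.4320441545
430	0.4425485977
431	0.4532511314
432	0.464142718
433	0.4752139398
434	0.4864550144
435	0.4978558109
436	0.509405866
437	0.5210944009
438	0.5329103391
439	0.5448423235
440	0.5568787346
441	0.5690077084
442	0.581217154
443	0.5934947711
444	0.605828068
445	0.6182043775
446	0.6306108742
447	0.6430345896
448	0.6554624273
449	0.6678811772
450	0.6802775284
451	0.692638082
452	0.7049493618
453	0.7171978247
454	0.7293698696
455	0.7414518455
456	0.7534300581
457	0.7652907757
458	0.7770202338
459	0.7886046388
460	0.8000301708
461	0.8112829858
462	0.8223492168
463	0.8332149747
464	0.8438663488
465	0.8542894069
466	0.8644701956
467	0.8743947409
468	0.8840490485
469	0.8934191062
470	0.9024908856
471	0.9112503463
472	0.919683441
473	0.9277761223
474	0.935514352
475	0.9428841123
476	0.9498714199
477	0.9564623431
478	0.962643022
479	0.9683996921
480	0.9737187115
481	0.9785865927
482	0.9829900376
483	0.986915977
484	0.990351615
485	0.9932844767
486	0.9957024615
487	0.9975938993
488	0.9989476118
489	0.9997529776
490	1
491	0.9996793787
492	0.9987825841
493	0.9973019333
494	0.9952306674
495	0.99256303
496	0.9892943447
497	0.985421092
498	0.9809409836
499	0.9758530337
500	0.970157626
501	0.963856575
502	0.9569531812
503	0.9494522781
504	0.9413602712
505	0.9326851665
506	0.9234365893
507	0.9136257909
508	0.9032656433
509	0.8923706224
510	0.8809567767
511	0.8690416845
512	0.8566443972
513	0.8437853708
514	0.8304863846
515	0.8167704485
516	0.8026617005
517	0.7881852937
518	0.7733672759
519	0.7582344616
520	0.7428142997
521	0.7271347364
522	0.7112240766
523	0.6951108444
524	0.6788236454
525	0.662391031
526	0.6458413675
527	0.6292027109
528	0.6125026881
529	0.5957683867
530	0.5790262538
531	0.562302004
532	0.5456205382
533	0.5290058733
534	0.5124810819
535	0.4960682438
536	0.4797884075
537	0.4636615624
538	0.4477066202
539	0.4319414062
540	0.4163826585
541	0.4010460346
542	0.3859461248
543	0.371096471
544	0.3565095903
545	0.3421970022
546	0.3281692576
547	0.3144359705
548	0.3010058498
549	0.2878867307
550	0.2750856055
551	0.2626086529
552	0.2504612652
553	0.2386480726
554	0.2271729654
555	0.2160391125
556	0.2052489782
557	0.1948043348
558	0.1847062742
559	0.1749552164
560	0.1655509171
561	0.1564924736
562	0.1477783315
563	0.1394062906
564	0.1313735125
565	0.1236765296
566	0.1163112569
567	0.1092730059
568	0.1025565027
569	0.09615590942
570	0.09006484931
571	0.08427643655
572	0.07878330958
573	0.07357766836
574	0.06865131526
575	0.06399569893
576	0.05960196083
577	0.05546098372
578	0.05156344149
579	0.04789984957
580	0.04446061542
581	0.04123608813
582	0.0382166068
583	0.03539254683
584	0.03275436376
585	0.03029263419
586	0.02799809338
587	0.02586166921
588	0.02387451244
589	0.02202802304
590	0.02031387262
591	0.01872402301
592	0.01725074109
593	0.01588660998
594	0.01462453695
595	0.01345775802
596	0.01237983987
597	0.01138467898
598	0.0104664986
599	0.009619843544
600	0.008839573406
601	0.008120854162
602	0.007459148643
603	0.006850206012
604	0.006290050495
605	0.005774969562
606	0.005301501753
607	0.004866424295
608	0.004466740655
609	0.004099668159
610	0.003762625767
611	0.003453222095
612	0.003169243765
613	0.002908644117
614	0.002669532348
615	0.0024501631
616	0.00224892652
617	0.002064338804
618	0.001895033241
619	0.001739751744
620	0.001597336878
621	0.00146672436
622	0.00134693603
623	0.001237073283
624	0.001136310921
625	0.001043891437
626	0.0009591196924
627	0.0008813579675
628	0.0008100213789
629	0.0007445736275
630	0.0006845230667
631	0.0006294190679
632	0.000578848665
633	0.0005324334583
634	0.0004898267615
635	0.0004507109745
636	0.0004147951651
637	0.0003818128455
638	0.0003515199284
639	0.0003236928501
640	0.0002981268463
641	0.000274634371
642	0.0002530436457
643	0.0002331973286
644	0.0002149512961
645	0.0001981735245
646	0.0001827430671
647	0.0001685491167
648	0.0001554901469
649	0.0001434731267
650	0.0001324128009
651	0.000122231032
652	0.0001128561979
653	0.0001042226406
654	9.627016194e-05
655	8.894356238e-05
656	8.219221883e-05
657	7.596969867e-05
658	7.023340656e-05
659	6.494426133e-05
660	6.006640052e-05
661	5.556690991e-05
662	5.141557629e-05
663	4.758466109e-05
664	4.404869339e-05
665	4.078428045e-05
666	3.776993442e-05
667	3.49859136e-05
668	3.241407735e-05
669	3.003775315e-05
670	2.784161492e-05
671	2.581157171e-05
672	2.393466566e-05
673	2.219897862e-05
674	2.059354667e-05
675	1.910828173e-05
676	1.773389978e-05
677	1.646185516e-05
678	1.528428023e-05
679	1.419393022e-05
680	1.318413254e-05
681	1.22487404e-05
682	1.138209023e-05
683	1.057896268e-05
684	9.834546764e-06
685	9.144407069e-06
686	8.504453585e-06
687	7.910914059e-06
688	7.3603086e-06
689	6.849426378e-06
690	6.37530422e-06
691	5.935206956e-06
692	5.526609367e-06
693	5.147179597e-06
694	4.794763912e-06
695	4.467372695e-06
696	4.163167567e-06
697	3.88044955e-06
698	3.617648181e-06
699	3.373311499e-06
700	3.146096834e-06
701	2.934762329e-06
702	2.738159147e-06
703	2.555224285e-06
704	2.384973969e-06
705	2.226497564e-06
706	2.078951974e-06
707	1.941556473e-06
708	1.813587952e-06
709	1.694376533e-06
710	1.583301529e-06
711	1.479787718e-06
712	1.383301909e-06
713	1.293349775e-06
714	1.209472929e-06
715	1.131246232e-06
716	1.058275299e-06
717	9.901942115e-07
718	9.266633901e-07
719	8.673676425e-07
720	8.120143548e-07
721	7.603318221e-07
722	7.120677067e-07
723	6.669876131e-07
724	6.24873771e-07
725	5.85523818e-07
726	5.487496741e-07
727	5.143765008e-07
728	4.822417387e-07
729	4.521942171e-07
730	4.240933295e-07
731	3.97808272e-07
732	3.732173367e-07
733	3.502072587e-07
734	3.286726113e-07
735	3.085152454e-07
736	2.896437705e-07
737	2.719730743e-07
738	2.554238766e-07
739	2.399223166e-07
740	2.253995701e-07
741	2.117914947e-07
742	1.990383006e-07
743	1.870842453e-07
744	1.758773505e-07
745	1.653691394e-07
746	1.555143928e-07
747	1.46270923e-07
748	1.375993634e-07
749	1.29462974e-07
750	1.218274595e-07
751	1.146608019e-07
752	1.079331034e-07
753	1.01616442e-07
754	9.568473559e-08
755	9.011361746e-08
756	8.488031903e-08
757	7.996356169e-08
758	7.534345592e-08
759	7.100140748e-08
760	6.692003019e-08
761	6.308306469e-08
762	5.947530296e-08
763	5.608251793e-08
764	5.289139808e-08
765	4.988948644e-08
766	4.706512383e-08
767	4.440739605e-08
768	4.190608453e-08
769	3.955162055e-08
770	3.733504239e-08
771	3.524795555e-08
772	3.328249554e-08
773	3.143129328e-08
774	2.968744277e-08
775	2.804447101e-08
776	2.649630984e-08
777	2.503726981e-08
778	2.366201561e-08
779	2.236554336e-08
780	2.114315919e-08
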