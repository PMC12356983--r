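# synthetic S sensitivity: Govardovskii A1 nomogram, corneal peak 419 nm, peak-normalized
wavelength_nm	value
380	0.6348934802
381	0.6477944417
382	0.6608016281
383	0.67389312
384	0.6870465488
385	0.7002391503
386	0.7134478155
387	0.7266491377
388	0.7398194561
389	0.7529348957
390	0.7659714025
391	0.778904776
392	0.7917106967
393	0.8043647502
394	0.8168424481
395	0.8291192455
396	0.8411705553
397	0.8529717604
398	0.8644982244
399	0.8757252998
400	0.8866283374
401	0.8971826939
402	0.9073637417
403	0.9171468798
404	0.9265075474
405	0.9354212408
406	0.9438635348
407	0.951810109
408	0.959236781
409	0.9661195451
410	0.9724346206
411	0.9781585071
412	0.9832680496
413	0.9877405134
414	0.9915536691
415	0.9946858873
416	0.9971162444
417	0.9988246386
418	0.9997919148
419	1
420	0.9994320459
421	0.9980725788
422	0.9959076552
423	0.9929250211
424	0.9891142731
425	0.9844670181
426	0.9789770316
427	0.9726404083
428	0.9654557056
429	0.9574240748
430	0.9485493779
431	0.9388382878
432	0.9283003682
433	0.9169481317
434	0.9047970733
435	0.8918656783
436	0.8781754037
437	0.8637506309
438	0.8486185923
439	0.8328092691
440	0.8163552656
441	0.7992916568
442	0.7816558169
443	0.7634872268
444	0.744827267
445	0.7257189982
446	0.706206932
447	0.6863367983
448	0.6661553096
449	0.6457099279
450	0.6250486358
451	0.6042197147
452	0.5832715322
453	0.5622523392
454	0.5412100779
455	0.5201922008
456	0.4992454989
457	0.4784159384
458	0.4577485055
459	0.4372870537
460	0.4170741553
461	0.3971509523
462	0.3775570054
463	0.3583301395
464	0.3395062854
465	0.3211193162
466	0.3032008806
467	0.2857802336
468	0.2688840692
469	0.2525363562
470	0.2367581849
471	0.221567627
472	0.2069796161
473	0.1930058541
474	0.1796547477
475	0.1669313814
476	0.1548375288
477	0.1433717054
478	0.1325292646
479	0.1223025341
480	0.1126809929
481	0.1036514832
482	0.09519845336
483	0.08730422618
484	0.07994928454
485	0.07311256871
486	0.06677177746
487	0.06090366657
488	0.05548433829
489	0.05048951651
490	0.0458948029
491	0.0416759107
492	0.03780887345
493	0.03427022738
494	0.03103716669
495	0.02808767207
496	0.02540061334
497	0.02295582766
498	0.0207341753
499	0.01871757492
500	0.01688902092
501	0.01523258511
502	0.013733405
503	0.01237766124
504	0.01115254592
505	0.01004622415
506	0.00904779022
507	0.008147220263
508	0.00733532248
509	0.00660368623
510	0.005944630864
511	0.005351155089
512	0.004816887481
513	0.004336038637
514	0.003903355304
515	0.003514076751
516	0.003163893556
517	0.002848908885
518	0.002565602318
519	0.002310796194
520	0.00208162443
521	0.001875503745
522	0.001690107175
523	0.001523339774
524	0.001373316384
525	0.001238341332
526	0.001116889942
527	0.001007591714
528	0.0009092150597
529	0.0008206534679
530	0.0007409129771
531	0.0006691008548
532	0.0006044153717
533	0.0005461365785
534	0.0004936179911
535	0.0004462791029
536	0.0004035986458
537	0.0003651085285
538	0.0003303883881
539	0.0002990606936
540	0.0002707863495
541	0.0002452607475
542	0.0002222102237
543	0.0002013888788
544	0.0001825757268
545	0.0001655721358
546	0.0001501995349
547	0.000136297356
548	0.0001237211899
549	0.0001123411321
550	0.0001020402999
551	9.271350305e-05
552	8.426605147e-05
553	7.661268644e-05
554	6.9676622e-05
555	6.33886853e-05
556	5.768654555e-05
557	5.251402243e-05
558	4.782046553e-05
559	4.356019758e-05
560	3.969201484e-05
561	3.61787385e-05
562	3.298681215e-05
563	3.008594015e-05
564	2.7448763e-05
565	2.505056556e-05
566	2.286901508e-05
567	2.08839256e-05
568	1.907704623e-05
569	1.743187084e-05
570	1.59334668e-05
571	1.456832103e-05
572	1.332420137e-05
573	1.219003192e-05
574	1.115578072e-05
575	1.021235866e-05
576	9.351528413e-06
577	8.565822372e-06
578	7.848468723e-06
579	7.193324774e-06
580	6.594816849e-06
581	6.047886073e-06
582	5.547939459e-06
583	5.090805765e-06
584	4.672695645e-06
585	4.290165666e-06
586	3.940085808e-06
587	3.619610098e-06
588	3.326150074e-06
589	3.057350793e-06
590	2.81106914e-06
591	2.5853542e-06
592	2.378429512e-06
593	2.188676993e-06
594	2.014622394e-06
595	1.854922131e-06
596	1.708351346e-06
597	1.573793102e-06
598	1.45022858e-06
599	1.336728196e-06
600	1.232443546e-06
601	1.136600097e-06
602	1.048490556e-06
603	9.674688547e-07
604	8.9294468e-07
605	8.243785164e-07
606	7.612771364e-07
607	7.031895054e-07
608	6.497030588e-07
609	6.004403176e-07
610	5.550558103e-07
611	5.132332733e-07
612	4.746831032e-07
613	4.391400379e-07
614	4.063610456e-07
615	3.761234025e-07
616	3.482229414e-07
617	3.22472456e-07
618	2.987002471e-07
619	2.767487961e-07
620	2.564735566e-07
621	2.377418514e-07
622	2.204318661e-07
623	2.044317312e-07
624	1.896386838e-07
625	1.759583018e-07
626	1.633038053e-07
627	1.515954172e-07
628	1.407597805e-07
629	1.307294238e-07
630	1.214422741e-07
631	1.128412105e-07
632	1.048736561e-07
633	9.749120431e-08
634	9.06492777e-08
635	8.430681454e-08
636	7.84259825e-08
637	7.297191621e-08
638	6.791247681e-08
639	6.321803158e-08
640	5.886125205e-08
641	5.481692872e-08
642	5.106180133e-08
643	4.757440302e-08
644	4.433491741e-08
645	4.132504745e-08
646	3.852789493e-08
647	3.592785e-08
648	3.351048953e-08
649	3.126248389e-08
650	2.917151119e-08
651	2.72261785e-08
652	2.541594944e-08
653	2.373107757e-08
654	2.216254513e-08
655	2.070200671e-08
656	1.934173739e-08
657	1.807458502e-08
658	1.689392629e-08
659	1.579362627e-08
660	1.476800116e-08
661	1.381178398e-08
662	1.292009291e-08
663	1.208840217e-08
664	1.131251515e-08
665	1.058853964e-08
666	9.912864961e-09
667	9.282140897e-09
668	8.693258258e-09
669	8.143330924e-09
670	7.629679279e-09
671	7.149814921e-09
672	6.70142653e-09
673	6.28236683e-09
674	5.890640526e-09
675	5.524393176e-09
676	5.181900889e-09
677	4.86156081e-09
678	4.561882323e-09
679	4.281478908e-09
680	4.019060614e-09
681	3.773427095e-09
682	3.543461162e-09
683	3.328122814e-09
684	3.126443718e-09
685	2.93752209e-09
686	2.760517957e-09
687	2.59464877e-09
688	2.439185335e-09
689	2.293448046e-09
690	2.156803388e-09
691	2.028660699e-09
692	1.908469168e-09
693	1.795715048e-09
694	1.689919069e-09
695	1.590634044e-09
696	1.497442639e-09
697	1.40995531e-09
698	1.327808386e-09
699	1.250662283e-09
700	1.178199855e-09
701	1.110124855e-09
702	1.046160506e-09
703	9.860481774e-10
704	9.295461477e-10
705	8.764284615e-10
706	8.264838613e-10
707	7.795147965e-10
708	7.353365014e-10
709	6.937761368e-10
710	6.546719914e-10
711	6.178727392e-10
712	5.832367472e-10
713	5.506314319e-10
714	5.199326588e-10
715	4.910241845e-10
716	4.63797136e-10
717	4.381495257e-10
718	4.139857998e-10
719	3.912164174e-10
720	3.697574573e-10
721	3.495302524e-10
722	3.304610484e-10
723	3.124806851e-10
724	2.955242996e-10
725	2.795310491e-10
726	2.644438524e-10
727	2.502091483e-10
728	2.367766705e-10
729	2.24099237e-10
730	2.121325537e-10
731	2.008350309e-10
732	1.901676118e-10
733	1.800936125e-10
734	1.705785722e-10
735	1.615901131e-10
736	1.530978101e-10
737	1.450730682e-10
738	1.37489008e-10
739	1.303203594e-10
740	1.235433608e-10
741	1.17135666e-10
742	1.110762568e-10
743	1.053453605e-10
744	9.992437341e-11
745	9.479578938e-11
746	8.99431321e-11
747	8.535089237e-11
748	8.100446908e-11
749	7.689011395e-11
750	7.299487977e-11
751	6.93065719e-11
752	6.581370281e-11
753	6.250544947e-11
754	5.93716134e-11
755	5.640258319e-11
756	5.358929941e-11
757	5.092322162e-11
758	4.839629751e-11
759	4.600093386e-11
760	4.372996932e-11
761	4.157664891e-11
762	3.953460002e-11
763	3.759780992e-11
764	3.576060461e-11
765	3.401762898e-11
766	3.236382819e-11
767	3.079443015e-11
768	2.930492906e-11
769	2.789106997e-11
770	2.654883425e-11
771	2.527442593e-11
772	2.406425889e-11
773	2.291494476e-11
774	2.182328161e-11
775	2.078624325e-11
776	1.98009692e-11
777	1.886475527e-11
778	1.797504464e-11
779	1.712941955e-11
780	1.632559337e-11
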