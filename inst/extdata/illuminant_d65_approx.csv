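# Approximate D65 daylight spectral power distribution:
# Planckian radiator at 6504 K normalised to 100 at 560 nm.
# Synthetic stand-in for the official CIE D65 table (smooth, no atmospheric bands).
"lambda_nm","power"
380,105.2488
385,106.3573
390,107.361
395,108.2626
400,109.0646
405,109.7699
410,110.3814
415,110.9021
420,111.3351
425,111.6835
430,111.9506
435,112.1396
440,112.2536
445,112.2959
450,112.2696
455,112.1778
460,112.0236
465,111.8101
470,111.5403
475,111.217
480,110.8431
485,110.4214
490,109.9546
495,109.4453
500,108.896
505,108.3093
510,107.6874
515,107.0326
520,106.3473
525,105.6334
530,104.8931
535,104.1283
540,103.3408
545,102.5326
550,101.7053
555,100.8606
560,100
565,99.1251
570,98.2373
575,97.3379
580,96.4283
585,95.5097
590,94.5833
595,93.6501
600,92.7114
605,91.7679
610,90.8208
615,89.8709
620,88.919
625,87.966
630,87.0126
635,86.0595
640,85.1074
645,84.1569
650,83.2086
655,82.263
660,81.3208
665,80.3822
670,79.4479
675,78.5183
680,77.5936
685,76.6744
690,75.7609
695,74.8534
700,73.9523
705,73.0578
710,72.1701
715,71.2895
720,70.4162
725,69.5503
730,68.6921
735,67.8417
740,66.9992
745,66.1648
750,65.3385
755,64.5205
760,63.7108
765,62.9096
770,62.1168
775,61.3326
780,60.5569
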