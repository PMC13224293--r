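"wavenumber","absorbance"
400,0.001301
440,0.002782
480,-0.002222
520,-0.001722
560,-0.002263
600,-0.002918
640,0.00016
680,0.001306
720,0.002402
760,0.00209
800,-0.002006
840,0.003697
880,-0.001334
920,0.000211
960,-0.000845
1000,-0.000245
1040,0.000376
1080,0.000238
1120,-5e-05
1160,0.000216
1200,-0.000971
1240,-0.001008
1280,-0.003322
1320,-0.000765
1360,-0.001025
1400,0.005404
1440,-0.002724
1480,0.000275
1520,-0.002987
1560,-0.002941
1600,0.000249
1640,-0.001993
1680,-4e-06
1720,-0.000857
1760,-0.001227
1800,-0.004049
1840,-0.002449
1880,0.000359
1920,0.001135
1960,-0.000986
2000,0
2040,0.002246
2080,0.00288
2120,-0.002194
2160,-0.000235
2200,0.002403
2240,-0.000939
2280,-0.000105
2320,-0.000172
2360,-0.001775
2400,-0.000889
2440,-5.8e-05
2480,-0.000811
2520,0.002501
2560,0.002004
2600,0.019929
2640,0.097246
2680,0.295491
2720,0.646767
2760,1.024407
2800,1.220396
2840,1.056601
2880,0.642723
2920,0.261992
2960,0.072457
3000,0.019405
3040,0.045477
3080,0.156821
3120,0.337251
3160,0.471942
3200,0.427195
3240,0.245715
3280,0.092404
3320,0.024516
3360,0.00131
3400,0.001231
3440,0.00019
3480,0.001792
3520,-0.00046
3560,0.001673
3600,-0.00349
3640,0.003379
3680,0.00173
3720,-0.000302
3760,-0.002898
3800,0.001286
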