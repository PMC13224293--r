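"wavenumber","absorbance"
400,0.001266
440,0.000809
480,-0.000212
520,0.003023
560,-0.000189
600,0.004037
640,-0.000125
680,0.00261
720,0.004573
760,-0.002778
800,-0.000558
840,-0.000267
880,0.001272
920,-0.000569
960,-0.005313
1000,-0.004881
1040,0.00264
1080,-0.000613
1120,-0.003551
1160,-0.000138
1200,0.004829
1240,0.02176
1280,0.085406
1320,0.26503
1360,0.520572
1400,0.664157
1440,0.536871
1480,0.280887
1520,0.094803
1560,0.022045
1600,0.001522
1640,0.001251
1680,-0.00342
1720,-0.001568
1760,-0.001702
1800,-0.004828
1840,7.2e-05
1880,0.000412
1920,-0.000722
1960,0.001516
2000,-0.001453
2040,-0.002737
2080,0.000866
2120,-0.001623
2160,0.002888
2200,-0.000863
2240,0.001311
2280,0.000644
2320,-0.001568
2360,0.003151
2400,0.001286
2440,0.00018
2480,0.000553
2520,0.001359
2560,0.00018
2600,-0.005986
2640,0.00057
2680,-0.000734
2720,0.00037
2760,0.001164
2800,0.002799
2840,-0.001454
2880,0.00262
2920,0.000942
2960,0.005266
3000,0.026144
3040,0.121892
3080,0.390963
3120,0.861698
3160,1.3079
3200,1.407586
3240,1.095486
3280,0.609585
3320,0.235652
3360,0.061618
3400,0.008604
3440,-0.001045
3480,0.003108
3520,0.00052
3560,0.000177
3600,-0.000242
3640,-0.002389
3680,0.001224
3720,-0.000434
3760,-0.000366
3800,0.001867
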