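"wavenumber","absorbance"
400,0.002147
440,0.008318
480,0.043729
520,0.147768
560,0.317935
600,0.446042
640,0.396969
680,0.2291
720,0.119979
760,0.161208
800,0.367552
840,0.603358
880,0.648461
920,0.44743
960,0.196571
1000,0.056177
1040,0.014964
1080,-0.000471
1120,-0.00414
1160,0.000552
1200,-0.001375
1240,0.000892
1280,-0.001625
1320,0.004424
1360,-0.000247
1400,-0.000955
1440,-0.000332
1480,0.001726
1520,0.000226
1560,-0.002764
1600,0.004914
1640,0.033404
1680,0.132479
1720,0.354
1760,0.601548
1800,0.658675
1840,0.463339
1880,0.210061
1920,0.057545
1960,0.01104
2000,0.001176
2040,-0.001418
2080,-0.002064
2120,-0.001261
2160,0.001174
2200,-0.000833
2240,-0.00157
2280,0.000327
2320,-0.002473
2360,0.002092
2400,-0.000969
2440,0.000378
2480,0.000102
2520,0
2560,0.003619
2600,-0.001651
2640,0.002291
2680,6.3e-05
2720,-0.00167
2760,-0.000138
2800,0.001494
2840,-0.000851
2880,-0.001544
2920,0.000306
2960,0.001977
3000,-0.000147
3040,-0.002774
3080,-0.002613
3120,-0.001537
3160,-0.001054
3200,-4.3e-05
3240,0.001341
3280,-0.000869
3320,-0.002228
3360,0.001214
3400,0.000551
3440,0.002315
3480,-0.003365
3520,0.000175
3560,0.002707
3600,0.001448
3640,-0.001665
3680,0.001465
3720,-0.001744
3760,-0.000907
3800,0.002375
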