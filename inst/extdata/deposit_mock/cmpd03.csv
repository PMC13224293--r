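"wavenumber","absorbance"
400,-0.001168
440,0.000738
480,0.000589
520,-0.000559
560,-0.002672
600,0.001401
640,0.001108
680,-0.001673
720,-0.003189
760,0.00041
800,-0.00069
840,0.000505
880,-0.002588
920,-0.001918
960,0.002172
1000,0.000808
1040,0.001173
1080,0.00363
1120,0.000258
1160,-0.004002
1200,0.000668
1240,0.002343
1280,0.004119
1320,-0.002754
1360,-0.002302
1400,-0.001412
1440,-0.002108
1480,-0.001291
1520,-0.000371
1560,-0.002402
1600,0.004074
1640,0.000216
1680,-0.000167
1720,0.001016
1760,0.00048
1800,0.004046
1840,0.032384
1880,0.128421
1920,0.35917
1960,0.651897
2000,0.750775
2040,0.55505
2080,0.261716
2120,0.081127
2160,0.01531
2200,0.00299
2240,-0.000299
2280,-0.00109
2320,0.005008
2360,0.017871
2400,0.088617
2440,0.259451
2480,0.506032
2520,0.628786
2560,0.50012
2600,0.258327
2640,0.083601
2680,0.018038
2720,0.000476
2760,-0.001255
2800,0.002007
2840,0.002517
2880,0.002498
2920,-0.002761
2960,0.004102
3000,0.002076
3040,0.000588
3080,0.007611
3120,0.036536
3160,0.150827
3200,0.390269
3240,0.635489
3280,0.66905
3320,0.452025
3360,0.191615
3400,0.052041
3440,0.009575
3480,-0.000958
3520,-0.000688
3560,0.001749
3600,0.001939
3640,0.000768
3680,-0.003703
3720,-0.000108
3760,0.00213
3800,0.001626
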