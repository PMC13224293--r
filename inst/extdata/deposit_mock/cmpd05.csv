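"wavenumber","absorbance"
400,-0.003153
440,-0.001698
480,-0.002177
520,-0.000969
560,-0.000673
600,-0.000307
640,-0.000486
680,0.003784
720,-0.002772
760,-0.00083
800,0.000698
840,0.003257
880,0.000177
920,0.002478
960,-0.003289
1000,0.002893
1040,-0.001381
1080,-0.000553
1120,-0.002219
1160,0.000268
1200,0.003571
1240,0.004844
1280,-0.002154
1320,0.000972
1360,0.002778
1400,-0.000377
1440,-0.000173
1480,0.002443
1520,0.023852
1560,0.110596
1600,0.330259
1640,0.643979
1680,0.806292
1720,0.649894
1760,0.333492
1800,0.110061
1840,0.025642
1880,0.004071
1920,0.00076
1960,-0.000496
2000,0.001863
2040,0.00267
2080,-0.001739
2120,0.000111
2160,9.8e-05
2200,-0.001157
2240,-0.001997
2280,-5e-06
2320,0.001311
2360,0.002955
2400,-0.003787
2440,-0.000925
2480,0.004101
2520,0.026471
2560,0.119031
2600,0.311295
2640,0.521622
2680,0.572247
2720,0.474763
2760,0.423823
2800,0.499757
2840,0.511254
2880,0.356013
2920,0.164162
2960,0.046931
3000,0.010834
3040,0.001199
3080,-0.001029
3120,0.000881
3160,0.000305
3200,-0.000329
3240,0.00404
3280,-0.001059
3320,-0.000942
3360,-0.003092
3400,-8.1e-05
3440,0.001781
3480,-0.004143
3520,-5e-04
3560,-0.002363
3600,0.002884
3640,0.002716
3680,0.000669
3720,0.002859
3760,-0.001735
3800,0.001901
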