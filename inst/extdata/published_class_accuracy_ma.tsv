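class	size	length_mean	length_std	similarity	ubcMEA_BL	ubcMFE_BL	gC_g1_BL	gC_pMFmeas_BL	rsMEA_T99	rsMFE_T99
16S Ribosomal RNA	675	485.66	113.02	0.62	0.625	0.645	0.630	0.665	0.561	0.521
23S Ribosomal RNA	159	453.44	117.85	0.57	0.645	0.643	0.626	0.664	0.588	0.562
5S Ribosomal RNA	128	120.98	3.21	0.88	0.782	0.780	0.763	0.782	0.616	0.630
Group I intron	89	368.49	103.58	0.63	0.644	0.631	0.642	0.670	0.576	0.550
Group II intron	2	578	47	0.72	0.540	0.609	0.524	0.582	0.472	0.471
Ribonuclease P RNA	399	332.78	52.34	0.72	0.643	0.603	0.656	0.678	0.615	0.575
Signal Recognition RNA	364	227.04	109.53	0.65	0.730	0.721	0.680	0.708	0.609	0.625
Transfer RNA	489	77.19	5.13	0.95	0.706	0.764	0.719	0.773	0.727	0.726
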