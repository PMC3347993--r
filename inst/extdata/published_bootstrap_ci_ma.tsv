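class	size	algorithm	lower	upper
16S Ribosomal RNA	675	ubcMEA	0.611	0.639
16S Ribosomal RNA	675	ubcMFE	0.630	0.660
16S Ribosomal RNA	675	rsMEA	0.548	0.574
16S Ribosomal RNA	675	rsMFE	0.507	0.536
16S Ribosomal RNA	675	gC_pMFmeas	0.652	0.679
23S Ribosomal RNA	159	ubcMEA	0.609	0.677
23S Ribosomal RNA	159	ubcMFE	0.607	0.677
23S Ribosomal RNA	159	rsMEA	0.556	0.618
23S Ribosomal RNA	159	rsMFE	0.530	0.593
23S Ribosomal RNA	159	gC_pMFmeas	0.633	0.693
5S Ribosomal RNA	128	ubcMEA	0.754	0.807
5S Ribosomal RNA	128	ubcMFE	0.751	0.806
5S Ribosomal RNA	128	rsMEA	0.573	0.657
5S Ribosomal RNA	128	rsMFE	0.586	0.671
5S Ribosomal RNA	128	gC_pMFmeas	0.758	0.804
Group I intron	89	ubcMEA	0.605	0.680
Group I intron	89	ubcMFE	0.594	0.666
Group I intron	89	rsMEA	0.540	0.611
Group I intron	89	rsMFE	0.513	0.587
Group I intron	89	gC_pMFmeas	0.634	0.704
Ribonuclease P RNA	399	ubcMEA	0.629	0.659
Ribonuclease P RNA	399	ubcMFE	0.588	0.618
Ribonuclease P RNA	399	rsMEA	0.602	0.628
Ribonuclease P RNA	399	rsMFE	0.561	0.588
Ribonuclease P RNA	399	gC_pMFmeas	0.665	0.690
Signal Recognition RNA	364	ubcMEA	0.708	0.750
Signal Recognition RNA	364	ubcMFE	0.698	0.742
Signal Recognition RNA	364	rsMEA	0.583	0.635
Signal Recognition RNA	364	rsMFE	0.599	0.651
Signal Recognition RNA	364	gC_pMFmeas	0.685	0.728
Transfer RNA	489	ubcMEA	0.683	0.723
Transfer RNA	489	ubcMFE	0.742	0.785
Transfer RNA	489	rsMEA	0.707	0.747
Transfer RNA	489	rsMFE	0.705	0.748
Transfer RNA	489	gC_pMFmeas	0.754	0.791
MA	2305	ubcMEA	0.664	0.680
MA	2305	ubcMFE	0.673	0.691
MA	2305	rsMEA	0.610	0.627
MA	2305	rsMFE	0.591	0.609
MA	2305	gC_pMFmeas	0.700	0.715
S-Full	3246	ubcMEA	0.673	0.688
S-Full	3246	ubcMFE	0.678	0.694
S-Full	3246	rsMEA	0.615	0.631
S-Full	3246	rsMFE	0.598	0.616
S-Full	3246	gC_pMFmeas	0.704	0.718
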