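class	size	length_mean	length_std	similarity	ubcMEA_BL	ubcMFE_BL	gC_g1_BL	gC_pMFmeas_BL	rsMEA_T99	rsMFE_T99
16S Ribosomal RNA	88	377.88	167.18	0.60	0.649	0.621	0.640	0.659	0.574	0.539
23S Ribosomal RNA	27	460.6	151.3	0.53	0.711	0.683	0.693	0.733	0.681	0.646
5S Ribosomal RNA	309	119.5	2.69	0.88	0.739	0.743	0.725	0.746	0.625	0.642
Group I intron	16	344.88	66.42	0.63	0.705	0.650	0.674	0.708	0.627	0.599
Group II intron	3	668.7	70.92	0.70	0.720	0.739	0.683	0.750	0.744	0.703
Ribonuclease P RNA	6	382.5	41.66	0.74	0.471	0.460	0.519	0.495	0.517	0.522
Signal Recognition RNA	91	267.95	61.72	0.71	0.641	0.621	0.633	0.637	0.518	0.557
Transfer RNA	484	77.48	4.8	0.96	0.718	0.775	0.727	0.782	0.726	0.727
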