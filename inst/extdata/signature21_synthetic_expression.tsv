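probe_id	gene_symbol	SYN1	SYN2	SYN3	SYN4
A_33_P3281850	CGREF1	7.7414	9.0387	9.4094	8.5358
A_23_P203972	FZD10	9.8891	12.225	10.4814	7.4771
A_23_P52017	ASPM	13.7557	9.373	12.1093	13.3591
A_23_P202587	SHTN1	10.2964	8.188	10.993	10.9372
A_23_P122197	CCNB1	8.0922	8.4525	11.685	6.6743
A_24_P303091	CXCL10	11.8596	9.5965	11.0438	10.7723
A_32_P4262	CFAP61	11.1517	10.8286	10.221	9.4269
A_23_P40078	XPO1	11.6083	9.3789	10.628	13.9769
A_23_P207400	BRCA1	8.1919	10.3204	7.4744	7.4
A_23_P325040	TMPO	8.4275	13.7553	10.9702	9.9283
A_23_P100127	CASC5	11.6899	8.9416	7.8262	9.3407
A_32_P106732	FANCM	8.1811	10.5863	6.7023	9.7336
A_23_P88630	BLM	6.7815	8.5913	7.9719	12.4949
A_33_P3372257	HOMER1	11.3109	13.6988	11.043	6.2214
A_33_P3370132	TNPO3	10.0072	10.052	9.4366	11.7528
A_23_P126120	CENPL	13.9955	10.2521	9.0787	7.7746
A_23_P71537	CSPP1	11.6145	8.764	7.7254	9.6101
A_33_P3246804	STARD3	11.4043	12.3223	10.3302	8.5723
A_33_P3286349	DNAAF3	9.2553	7.7286	6.6819	6.2927
A_23_P132277	MCM5	11.0711	13.285	7.0481	13.7975
A_24_P148151	TSNAX	11.4268	13.5324	13.0989	9.0984
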