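patient	array	trp_start	trp_size	dup_start	dup_size	microhomology	insertion	blunt	chimeric_elements	repeat_elements	denovo_mutations	flags
P250	NimbleGen	103145195	78476	102866025	458310	-gagTTGActg-	-g(a)gTTGActg-	N/A	N/A	MER101 // N/A	1	
P298	Affymetrix	103223417	254	102943388	380947	-aacAAtgc-	N/A	N/A	N/A	N/A	0	
BAB1612/P374	Affymetrix	103198235	25436	103179140	145195	-aagAGGTtcc-	N/A	N/A	N/A	L2c (LCR) // L2c (same LCR)	0	
P500	NimbleGen/Agilent	103073314	150357	102723607	600728	-ctcTAGctt... ...aggtcatttat-	93bp of 102739366(+)...ggt(c)attt(a)t-	N/A	N/A	L1ME4a // HAL1b // L2	0	
P518	NimbleGen	103004306	219365	102324702	999633	-ggcCT...ACcat... ...atTA...AAtta-	488bp of 103003940(+)	N/A	AluS (34bp) / AluS (14bp)	AluSq // AluSx...AluSq // AluSg	0	
P558	NimbleGen	103149848	73823	102804340	519995	N/A	N/A	-ttgg/tctg-	N/A	L1PA2 // MIR	0	
P642	NimbleGen	102648490	575181	102627018	697317	-ggtAGcct-	N/A	N/A	N/A	L1M4c // N/A	0	
P674	NimbleGen	102963070	260601	102793421	530914	-actAggc-	N/A	N/A	N/A	N/A	0	
P820	NimbleGen	102847223	376448	102770530	553805	-tagGAGaAAggt-	N/A	N/A	N/A	L1PA7 // MIRb	0	
P842	NimbleGen	103196894	26777	102642482	681853	N/A	N/A	-gaaa/ttct-	N/A	L1ME3B // AluSc	0	
P1150	NimbleGen	103019045	204626	102803592	520743	-ttcAGgaa-	N/A	N/A	N/A	HERVH // L1MA9	0	
P1389	Affymetrix	103180817	42854	102885051	439284	-ggaGcag-	N/A	N/A	N/A	LCR // N/A	0	
P1407	Affymetrix/Agilent	103088384	135287	102744808	579527	-agcaTGctca-	N/A	N/A	N/A	L2a // N/A	0	
BAB1290	Agilent	103128008	95663	102528713	795622	-atgATTTagg... ...ttttatagc-	43bp of 102550108(+), ...ttt(tat)agc-	N/A	N/A	L1PA3 // L1MB4 // L1M5	0	
BAB2389	Agilent	103081145	142528	99388802	3935533	-aaaCtgg... ...cttTATact-	57bp of 103093622(-)	N/A	N/A	N/A // N/A // L1MEc	0	trp_size_inconsistent_with_endpoints
BAB3698	Agilent	102995680	227991	102944787	379548	-taggGATGG... ...GACCTcagg-	N/A	N/A	AluSx (47 bp identity)	AluSx // AluSx	0	
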