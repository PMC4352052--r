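individual	haplotype	alleles
IND01	1	ACGTACGT
IND01	2	ACGTACGT
IND02	1	ACGTACGT
IND02	2	ACGTACGT
IND03	1	ACGTACGT
IND03	2	ACGTACGT
IND04	1	GTACGTAC
IND05	1	ACGTACGT
IND05	2	GTACGTAC
IND06	1	GTACGTAC
IND06	2	GTACGTAC
IND07	1	ACGTACGT
IND07	2	ACGTACGT
IND08	1	GTACGTAC
IND08	2	GTACGTAC
IND09	1	ACGTACGT
IND09	2	GTACGTAC
IND10	1	ACGTACGT
IND11	1	GTACGTAC
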