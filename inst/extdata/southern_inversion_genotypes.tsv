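individual	sex	genotype	population
IND01	F	H2	J
IND02	F	H2	H
IND03	F	H2	Y
IND04	M	H2	CEU
IND05	F	H1	J
IND06	F	H1	H
IND07	F	H1	Y
IND08	F	H1	CEU
IND09	F	H1	U
IND10	M	H1	J
IND11	M	H1	H
IND12	F	H1/H2	Y
IND13	F	H1/H2	CEU
IND14	F	H1/H2	J
IND15	F	H1/H2	H
IND16	F	H1/H2	Y
IND17	F	H1/H2	U
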