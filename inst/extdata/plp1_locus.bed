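chrX	103031756	103047547	gene	0	+
chrX	103171386	103211386	C	0	+
chrX	103220170	103220670	southern_probe	0	+
chrX	103223670	103244020	A1a	0	+
chrX	103254000	103264000	A2	0	+
chrX	103284000	103294000	A3	0	-
chrX	103324334	103344684	A1b	0	-
chrX	103356684	103396684	D	0	-
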