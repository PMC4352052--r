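chrom	start1	end1	strand1	start2	end2	strand2	clone	individual
chrX	103150000	103150500	+	103189500	103190000	-	G248_c1	G248
chrX	103221000	103221500	+	103246000	103246500	+	G248_c2	G248
chrX	103321800	103322300	-	103345500	103346000	-	G248_c3	G248
chrX	103120000	103120500	+	103159500	103160000	-	ABC10_c1	ABC10
chrX	103220400	103220900	+	103247100	103247600	+	ABC10_c2	ABC10
chrX	103321000	103321500	-	103346200	103346700	-	ABC10_c3	ABC10
chrX	103221700	103222200	+	103245300	103245800	+	ABC11_c1	ABC11
chrX	103320500	103321000	-	103345100	103345600	-	ABC11_c2	ABC11
chrX	103140000	103140500	+	103179500	103180000	-	ABC11_c3	ABC11
chrX	103220900	103221400	+	103246800	103247300	+	ABC12_c1	ABC12
chrX	103322300	103322800	-	103346900	103347400	-	ABC12_c2	ABC12
chrX	103219800	103220300	+	103245900	103246400	+	ABC13_c1	ABC13
chrX	103321500	103322000	-	103345800	103346300	-	ABC13_c2	ABC13
chrX	103100000	103100500	+	103139500	103140000	-	ABC13_c3	ABC13
chrX	103220700	103221200	+	103246300	103246800	+	ABC7_c1	ABC7
chrX	103130000	103130500	+	103169500	103170000	-	ABC7_c2	ABC7
chrX	103321200	103321700	-	103346500	103347000	-	ABC8_c1	ABC8
chrX	103110000	103110500	+	103149500	103150000	-	ABC8_c2	ABC8
chrX	103221300	103221800	+	103245500	103246000	+	ABC14_c1	ABC14
chrX	103125000	103125500	+	103164500	103165000	-	ABC14_c2	ABC14
chrX	103135000	103135500	+	103174500	103175000	-	ABC9_c1	ABC9
chrX	103105000	103105500	+	103144500	103145000	-	ABC9_c2	ABC9
chrX	102900000	102900500	+	102901500	102902000	+	ABC9_c3	ABC9
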