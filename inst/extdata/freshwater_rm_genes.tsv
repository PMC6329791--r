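genome_id	gene_id	contig_id	gene_index	role	top_hit	identity_pct	motif	meth_offset	mod_type	rm_type	rm_system_reported	trd_divergence	motif_detected_reported	mtase_name	confirmed_motif
BS3	EMGBS3_04270	BS3_c1	427	M	M.SstE37II	58.9	GANTC	1	m6A	II	No	No	Yes		
BS3	EMGBS3_09240	BS3_c1	924	M	M.Sth20745I	71.4	TTAA	3	m6A	II	No	No	Yes		
BS3	EMGBS3_12600	BS3_c1	1260	M	M1.BceSIII	22.9	ACGGC	1	m4C	II	No	Yes	No	M.AbaBS3I	GCWGC
BS6	EMGBS6_08960	BS6_c1	896	M	M.SinI	57.0	GGWCC	3	m5C	II	No	No	No		
BS8	EMGBS8_10720	BS8_c1	1072	R	DvuI	36.3	?	NA	-	I	-	-	-		
BS8	EMGBS8_10740	BS8_c1	1074	S	S.PveNS15I	32.4	?	NA	-	I	-	Yes	-		
BS8	EMGBS8_10750	BS8_c1	1075	M	M.RbaNRL2II	55.6	ACGANNNNNNGRTC	3	m6A	I	Yes	-	No		
BS10	EMGBS10_10070	BS10_c1	1007	M	RM.CjeFIII	23.7	GCAAGG	3	m6A	II	Yes	Yes	No	M.ObaBS10I	ACGAG
BS14	EMGBS14_10020	BS14_c1	1002	M	M.Bsp460I	56.7	GANTC	1	m6A	II	No	No	Yes		
BS15	EMGBS15_02830	BS15_c1	283	M	M.Bli37I	56.6	GAYNNNNNRTC	1	m6A	I	Yes	-	No		
BS15	EMGBS15_02840	BS15_c1	284	M	M.EcoNIH1III	59.2	GATGNNNNNNTAC	1	m6A	I	Yes	-	No		
BS15	EMGBS15_02870	BS15_c1	287	S	S.PveNS15I	47.2	?	NA	-	I	-	Yes	-		
BS15	EMGBS15_02930	BS15_c1	293	R	DvuI	38.4	?	NA	-	I	-	-	-		
BS15	EMGBS15_03820	BS15_c1	382	M	M.EcoGI	25.8	Nonspecific	NA	m6A	II	Yes	Yes	No	M.FspBS16I	GAANNNNTTC
BS15	EMGBS15_03830	BS15_c1	383	R	XmnI	34.0	GAANNNNTTC	NA	-	II	-	-	-		
BS15	EMGBS15_04560	BS15_c1	456	R	GmeII	33.8	TCCAGG	NA	-	III	-	-	-		
BS15	EMGBS15_04600	BS15_c1	460	M	M.FpsJII	53.4	CGCAG	3	m6A	III	Yes	No	No		
BS15	EMGBS15_05670	BS15_c1	567	M	M.FnuDI	59.8	GGCC	NA	m4C	II	Yes	No	No		
BS15	EMGBS15_05690	BS15_c1	569	R	BhaII	45.6	GGCC	NA	-	II	-	-	-		
BS15	EMGBS15_12460	BS15_c1	1246	M	M.Mva1261III	37.1	CTANNNNNNRTTC	2	m6A	I	No	No	No		
BD1	EMGBD1_08400	BD1_c1	840	M	M.Sth20745I	71.0	TTAA	3	m6A	II	No	No	Yes		
BD1	EMGBD1_09320	BD1_c1	932	M	M1.BceSIII	22.9	ACGGC	1	m4C	II	No	Yes	No	M.AbaBS3I	GCWGC
BD1	EMGBD1_19510	BD1_c1	1951	M	M.SstE37II	58.9	GANTC	1	m6A	II	No	No	Yes		
BD2	EMGBD2_08760	BD2_c1	876	M	M.HgiDII	55.0	GTCGAC	NA	m5C	II	Yes	No	No		
BD2	EMGBD2_08790	BD2_c1	879	M	RM.AquIV	28.5	GRGGAAG	5	m6A	II	Yes	Yes	No	M.NbaBD2I	TAHGGAB
BD2	EMGBD2_08800	BD2_c1	880	R	LpnPI	56.3	CCDG	NA	-	II	-	-	-		
BD3	EMGBD3_00670	BD3_c1	67	M	M.Mma5219II	45.9	AGCT	2	m4C	II	No	No	Yes		
BD3	EMGBD3_01960	BD3_c1	196	M	M.AvaVI	50.3	GATC	1	m6A	II	No	No	Yes		
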