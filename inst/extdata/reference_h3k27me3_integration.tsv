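gene_accession	gene_id	expr_log2fc	mark_log2fc
NM_010074	Dpp4	-16.003	-1.34722077
NM_172463	Sned1	-6.257	-1.16715932
NM_008259	Foxa1	-5.241	-1.82107269
NM_175473	Fras1	-5.204	-1.19562114
NM_021331	G6pc2	-4.957	-1.10028594
NM_010501	Ifit3	-4.716	-1.78884336
NM_028894	Lonrf3	-4.574	-1.54787003
NM_001025570	Prrx1	-2.683	-1.28457282
NM_001163098	Tchh	-1.47	-1.43213155
NM_031176	Tnxb	-3.899	1.30043346
NM_007467	Aplp1	1.128	-1.05803508
NM_010118	Egr2	1.409	-1.99831957
NM_025980	Nrarp	5.588	-1.96283384
NM_001008793	Whrn	12.943	-2.75133723
NM_021279	Wnt1	13.997	-1.10023151
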