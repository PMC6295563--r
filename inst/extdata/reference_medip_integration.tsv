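gene_accession	gene_id	expr_log2fc	mark_log2fc
NM_016687	Sfrp4	-4.59	-1.07348337
NM_026257	Ubxn11	-3.457	-1.03471761
NM_175199	Hspa12a	-3.145	-1.46219747
NM_013460	Adrald	-2.851	-1.38134037
NM_008714	Notch1	-1.568	-1.53733423
NM_009359	Tex9	-1.225	-1.12112261
NM_010806	Afdn	-0.776	-1.51548783
NM_146155	Ahdd	-0.726	-1.03777499
NM_029348	Zbtb4	-0.64	-2.07882427
NM_178878	Hadha	-0.555	-1.40843417
NM_173741	Wdr24	-0.537	-1.08835819
NM_133740	Prmt3	0.522	1.27886894
NM_001008421	Nol10	0.62	1.34590795
NM_008084	Gapdh	0.836	1.51507841
NM_007400	Adam12	3.106	1.18884493
NM_008909	Ppl	-3.537	1.02814109
NM_009931	Col4a1	-1.111	1.18884493
NM_028200	Vps9d1	-0.89	1.32210035
NM_033563	Klf7	-0.633	1.48896494
NM_054044	Adgra2	-0.392	1.62011388
NM_009211	Smarcd	0.608	-1.04303283
NM_172585	Larp4b	0.608	-1.47577455
NM_001081321	Pds5a	0.644	-1.03048504
NM_024452	Luzp1	0.747	-1.27570871
NM_178661	Creb3l2	0.837	-1.08859245
NM_024472	Cptp	0.862	-1.27774791
NM_177644	Rasal2	1.228	-1.14013994
NM_144515	Zfp52	1.257	-1.33247327
NM_028778	Nuak2	1.581	-1.20811393
NM_153287	Csrnp1	1.748	-1.30599888
NM_026473	Tubb6	1.983	-1.15399286
NM_008120	Gja4	3.703	-1.38683764
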