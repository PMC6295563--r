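gene_id	symbol	rank_control	rank_treated
NM_001004174	AA467197	1	4
NM_053080	Aldh1a3	1	4
NM_009865	Cdh10	1	4
NM_030209	Crispld2	1	4
NM_177914	Dgkk	1	4
NM_008216	Has2	1	4
NM_053105	Klhl1	1	4
NM_027551	Klhl30	1	4
NM_001001985	Nat8l	1	4
NM_175093	Trib3	1	4
NM_153543	Aldh1l2	2	5
NM_007735	Col4a4	2	5
NM_016919	Col5a3	2	5
NM_001081437	Fbln2	2	5
NM_023279	Tubb3	2	5
NM_139298	Wnt9a	2	5
NM_007428	Agt	5	1
NM_009778	C3	5	1
NM_016675	Cldn2	5	1
NM_011339	Cxcl15	5	1
NM_008597	Mgp	5	1
NM_026864	Rasl11a	5	1
NM_053116	Wnt16	5	1
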