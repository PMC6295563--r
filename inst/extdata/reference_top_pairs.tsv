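mirna_id	mirna_direction	gene_id	gene_direction	relationship
mmu-miR-351-5p	down	Tnfsf4	up	-6.67570546
mmu-miR-485-5p	up	Atoh8	down	-3.93438238
mmu-miR-130b-3p	down	Pmepa1	up	-3.76454559
mmu-miR-485-5p	up	Clic5	down	-3.69006107
mmu-miR-26a-5p	down	Cd200	up	-3.38661889
mmu-miR-130a-3p	down	Pmepa1	up	-3.113305
mmu-miR-130b-3p	down	Nox4	up	-2.51621015
mmu-miR-351-5p	down	Sema4f	up	-2.31908499
mmu-miR-96-5p	up	Pard3b	down	-2.28866038
mmu-miR-130a-3p	down	Nox4	up	-2.08092303
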