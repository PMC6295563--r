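mirna_id	direction	n_targets
mmu-miR-532	down	4
mmu-miR-503	down	1
mmu-miR-351	down	12
mmu-miR-27a	down	21
mmu-miR-26a	down	9
mmu-miR-200a	down	11
mmu-miR-130a	down	12
mmu-miR-130b	down	23
mmu-miR-433	up	7
mmu-miR-96	up	13
mmu-miR-485	up	14
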