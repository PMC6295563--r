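mirna_id	fold_change	abs_log2fc	direction
mmu-miR-127-3p	2.06	1.04	up
mmu-miR-181a-2-3p	2.08	1.06	up
mmu-miR-379-5p	2.22	1.15	up
mmu-miR-183-3p	2.39	1.25	up
mmu-miR-485-5p	2.42	1.27	up
mmu-miR-96-5p	2.56	1.36	up
mmu-miR-433-3p	2.77	1.47	up
mmu-miR-200a-3p	0.10	3.36	down
mmu-miR-3099-3p	0.16	2.66	down
mmu-miR-503-5p	0.20	2.33	down
mmu-miR-181c-3p	0.23	2.13	down
mmu-miR-351-5p	0.24	2.04	down
mmu-miR-351-3p	0.26	1.94	down
mmu-miR-101a-3p	0.27	1.91	down
mmu-miR-27a-3p	0.29	1.80	down
mmu-miR-26a-5p	0.36	1.48	down
mmu-miR-130a-3p	0.41	1.29	down
mmu-miR-130b-3p	0.48	1.07	down
mmu-miR-532-5p	0.49	1.02	down
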