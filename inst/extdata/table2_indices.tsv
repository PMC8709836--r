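# Per-population polymorphism index rows as printed (see provenance notes in
# table2_genotypes.tsv for the column alignment). panel = 1 marks the ten
# populations admitted to quantitative analysis (more than 10 specimens).
population	n_larvae	panel	n_sequences	n_genotypes	pct_het_larvae	het_inv_per_larva
YAR-RY	100	1	7	7	0	0
YAR-RY-OWN	4	0	7	7	0	0
NSK-BE	45	1	9	10	44.4	0.467
NSK-EL	4	0	9	9	50.0	0.500
NSK-KA	34	1	9	10	58.8	0.676
NSK-SH	259	1	12	14	60.6	0.684
NSK-2R	14	1	9	9	50.0	0.572
NSK-SP	1	0	7	7	0	0
NSK-LI	32	1	9	11	73.1	0.937
NSK-CH	2	0	7	7	0	0
NSK-SA	5	0	7	7	0	0
NSK-OR	52	1	9	10	50.0	0.596
NSK-YU	151	1	9	11	52.3	0.576
NSK-ST	54	1	10	11	59.3	0.685
KEM-TA	1	0	7	7	0	0
ALT-GI	1	0	7	7	0	0
ALT-TR	3	0	9	9	66.7	1.0
YAK-SO	2	0	8	8	50.0	0.500
KHA-EV	36	1	8	8	2.8	0.028
KHA-AM	2	0	8	8	0	0
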