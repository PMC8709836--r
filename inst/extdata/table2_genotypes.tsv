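# Frequencies of genotypic combinations of banding sequences, as printed.
# Provenance notes:
# - The printed table carries 20 data columns under 19 site headers. Column
#   YAR-RY is the previously published Rybinsk Reservoir sample (n = 100)
#   that enters the quantitative panel; YAR-RY-OWN is this study's own
#   probes from the same site (n = 4, Table 1). The remaining columns follow
#   the site order of the header (YAK-SO before KHA-EV and KHA-AM).
# - The printed arm-E heterozygote row is labelled "h'agiF1.p'agiE2"; it sits
#   in the arm-E block and mixes arms, and is stored here corrected as
#   h'agiE1.p'agiE2.
# - Some non-panel columns are internally inconsistent with the text and
#   with the frequency table (e.g. NSK-CH monomorphic for p'agiB1 although
#   all Siberian populations are described as p'agiB2-dominant); values are
#   kept exactly as printed.
genotype	YAR-RY	YAR-RY-OWN	NSK-BE	NSK-EL	NSK-KA	NSK-SH	NSK-2R	NSK-SP	NSK-LI	NSK-CH	NSK-SA	NSK-OR	NSK-YU	NSK-ST	KEM-TA	ALT-GI	ALT-TR	YAK-SO	KHA-EV	KHA-AM
n	100	4	45	4	34	259	14	1	32	2	5	52	151	54	1	1	3	2	36	2
p'agiA1.1	1	1	1	0.750	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
p'agiA1.2	0	0	0	0.250	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
p'agiB1.1	1	1	0.044	0	0.029	0.042	0	0	0.031	1	0	0.019	0.007	0.056	0	0	0	0.500	0	0.500
p'agiB2.2	0	0	0.689	1	0.471	0.456	0.571	1	0.313	0	1	0.712	0.702	0.481	1	1	0.667	0	1	0.500
p'agiB1.2	0	0	0.267	0	0.500	0.498	0.429	0	0.656	0	0	0.269	0.291	0.463	0	0	0.333	0.500	0	0
p'agiB2.3	0	0	0	0	0	0.004	0	0	0	0	0	0	0	0	0	0	0	0	0	0
h'agiC1.1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0.333	1	1	1
h'agiC1.p'agiC2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0.667	0	0	0
p'agiD1.1	1	1	1	1	1	0.996	1	1	1	1	1	1	1	0.981	1	1	1	1	0.972	1
p'agiD1.2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0.028	0
p'agiD1.3	0	0	0	0	0	0.004	0	0	0	0	0	0	0	0.019	0	0	0	0	0	0
h'agiE1.1	1	1	1	1	1	0.996	1	1	1	1	1	1	1	1	1	1	1	1	1	1
h'agiE1.p'agiE2	0	0	0	0	0	0.004	0	0	0	0	0	0	0	0	0	0	0	0	0	0
p'agiF1.1	1	1	0.800	0.750	0.824	0.822	0.857	1	0.656	1	1	0.673	0.709	0.778	0	0	0	0	1	1
p'agiF2.2	0	0	0	0	0	0	0	0	0.063	0	0	0	0.007	0	0	0	0	0	0	0
p'agiF1.2	0	0	0.200	0.250	0.176	0.174	0.143	0	0.281	0	0	0.327	0.284	0.222	1	1	1	1	0	0
p'agiF1.3	0	0	0	0	0	0.004	0	0	0	0	0	0	0	0	0	0	0	0	0	0
p'agiG1.1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
B-chromosome	0	0	0	0	0	0.050	0	0	0	0	0	0.038	0	0	0	0	0	0	0	0
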