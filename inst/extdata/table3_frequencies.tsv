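# Frequencies of banding sequences in the ten populations with more than 10
# specimens, as printed. Provenance note: the NSK-LI and NSK-OR columns are
# mutually inconsistent with the printed distance matrix (each reproduces the
# other's row, suggesting swapped labels); both tables are kept as printed.
sequence	YAR-RY	NSK-BE	NSK-KA	NSK-SH	NSK-2R	NSK-LI	NSK-OR	NSK-YU	NSK-ST	KHA-EV
n	100	45	34	259	14	32	52	151	54	36
p'agiA1	1	1	1	1	1	1	1	1	1	1
p'agiA2	0	0	0	0	0	0	0	0	0	0
p'agiB1	1	0.178	0.279	0.291	0.214	0.359	0.154	0.152	0.288	0
p'agiB2	0	0.822	0.721	0.707	0.786	0.641	0.846	0.848	0.712	1
p'agiB3	0	0	0	0.002	0	0	0	0	0	0
h'agiC1	1	1	1	1	1	1	1	1	1	1
p'agiC2	0	0	0	0	0	0	0	0	0	0
p'agiD1	1	1	1	0.998	1	1	1	1	0.991	0.986
p'agiD2	0	0	0	0	0	0	0	0	0	0.014
p'agiD3	0	0	0	0.002	0	0	0	0	0.009	0
h'agiE1	1	1	1	0.996	1	1	1	1	1	1
p'agiE2	0	0	0	0.004	0	0	0	0	0	0
p'agiF1	1	0.900	0.912	0.911	0.929	0.797	0.837	0.851	0.889	1
p'agiF2	0	0.100	0.088	0.087	0.071	0.203	0.163	0.149	0.111	0
p'agiF3	0	0	0	0.002	0	0	0	0	0	0
p'agiG1	1	1	1	1	1	1	1	1	1	1
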