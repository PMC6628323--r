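amino_acid	codon	ttsuv1	ttsuv2	sus_scrofa	sus_scrofa_domestica
F	TTT	1.1	1.2	0.79	0.59
F	TTC	0.9	0.8	1.21	1.41
L	TTA	0.93	1.73	0.32	0.3
L	TTG	0.32	0.21	0.67	0.49
L	CTT	0.79	0.57	1.35	1.41
L	CTC	0.99	1.51	1.35	1.41
L	CTA	1.74	1.68	0.33	0.28
L	CTG	1.22	0.29	2.68	2.92
I	ATT	0.84	0.54	0.91	1.22
I	ATC	0.6	0.49	1.67	1.45
I	ATA	1.56	1.97	0.42	0.34
V	GTT	0.55	0.65	0.57	0.34
V	GTC	0.6	0.6	1.07	1.45
V	GTA	1.81	2.24	0.34	0.17
V	GTG	1.04	0.51	2.03	2.04
S	TCT	0.96	0.71	0.99	1.1
S	TCC	0.83	0.6	1.5	1
S	TCA	1.28	1.51	0.73	2.45
S	TCG	0.59	0.15	0.39	0.55
S	AGT	1.61	1.02	0.77	0.25
S	AGC	0.73	2	1.62	0.66
P	CCT	0.6	1.57	1.05	0.84
P	CCC	0.86	0.42	1.46	1.59
P	CCA	1.9	0.64	0.94	0.91
P	CCG	0.65	0.71	0.56	0.66
T	ACT	0.69	2.33	0.83	0.77
T	ACC	0.65	0.31	1.68	1.2
T	ACA	2.08	1.14	0.92	1.62
T	ACG	0.58	0.48	0.57	0.41
A	GCT	0.76	2.16	0.96	0.7
A	GCC	1.07	0.22	1.8	1.03
A	GCA	1.6	1.03	0.74	1.92
A	GCG	0.57	0.98	0.5	0.36
Y	TAT	0.57	1.14	0.73	0.69
Y	TAC	1.43	0.86	1.27	1.31
H	CAT	0.56	0.72	0.7	0.6
H	CAC	1.44	1.28	1.3	1.4
Q	CAA	0.81	1.5	0.44	0.29
Q	CAG	1.19	0.5	1.56	1.71
N	AAT	0.77	0.93	0.79	0.82
N	AAC	1.23	1.07	1.21	1.18
K	AAA	1.38	1.6	0.76	0.91
K	AAG	0.62	0.4	1.24	1.09
D	GAT	0.6	0.75	0.8	0.81
D	GAC	1.4	1.25	1.2	1.19
E	GAA	1.22	1.39	0.72	1.24
E	GAG	0.78	0.61	1.28	0.76
C	TGT	0.88	1.3	0.79	0.81
C	TGC	1.12	0.7	1.21	1.19
R	CGT	0.48	0.15	0.44	0.4
R	CGC	0.88	0.95	1.31	1.09
R	CGA	0.82	0.64	0.6	0.27
R	CGG	0.3	0.52	1.29	0.77
R	AGA	2.8	2.95	1.12	2.75
R	AGG	0.71	0.79	1.23	0.71
G	GGT	0.62	0.32	0.57	0.31
G	GGC	0.55	0.5	1.46	0.84
G	GGA	2.21	2.74	0.91	1.78
G	GGG	0.61	0.44	1.05	1.07
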