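# Per-residue physicochemical scales used by encoding_scheme("physchem").
# Columns (standardized to zero mean / unit variance over the 20 residues
# at load time):
#   volume        side-chain volume, A^3 (Zamyatnin 1972)
#   polarity      polarity index (Grantham 1974)
#   isoelectric   isoelectric point pI (Zimmerman et al. 1968)
#   hydrophobicity  hydropathy index (Kyte & Doolittle 1982)
#   accessibility mean accessible surface area in extended tripeptide, A^2
#                 (Chothia 1976 / Miller et al. 1987 consensus values)
residue	volume	polarity	isoelectric	hydrophobicity	accessibility
A	88.6	8.1	6.00	1.8	115
C	108.5	5.5	5.05	2.5	135
D	111.1	13.0	2.77	-3.5	150
E	138.4	12.3	3.22	-3.5	190
F	189.9	5.2	5.48	2.8	210
G	60.1	9.0	5.97	-0.4	75
H	153.2	10.4	7.59	-3.2	195
I	166.7	5.2	6.02	4.5	175
K	168.6	11.3	9.74	-3.9	200
L	166.7	4.9	5.98	3.8	170
M	162.9	5.7	5.74	1.9	185
N	114.1	11.6	5.41	-3.5	160
P	112.7	8.0	6.30	-1.6	145
Q	143.8	10.5	5.65	-3.5	180
R	173.4	10.5	10.76	-4.5	225
S	89.0	9.2	5.68	-0.8	115
T	116.1	8.6	5.66	-0.7	140
V	140.0	5.9	5.96	4.2	155
W	227.8	5.4	5.89	-0.9	255
Y	193.6	6.2	5.66	-1.3	230
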