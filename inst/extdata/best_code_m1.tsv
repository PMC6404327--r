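codon	group	psi	phi_num	phi_den	phik_num	phik_den
AAA	g01	1	2	3	2	3
AAT	g01	1	2	3	2	3
AAG	g01	1	2	3	2	3
AAC	g01	1	2	3	2	3
CGA	g02	1	2	3	2	3
CGT	g02	1	2	3	2	3
CGG	g02	1	2	3	2	3
CGC	g02	1	2	3	2	3
ACA	g03	1	2	3	2	3
ACT	g03	1	2	3	2	3
ACG	g03	1	2	3	2	3
ACC	g03	1	2	3	2	3
GTA	g04	1	2	3	2	3
GTT	g04	1	2	3	2	3
GTG	g04	1	2	3	2	3
GTC	g04	1	2	3	2	3
CAA	g05	1	2	3	2	3
CAT	g05	1	2	3	2	3
CAG	g05	1	2	3	2	3
CAC	g05	1	2	3	2	3
AGA	g06	1	2	3	2	3
AGT	g06	1	2	3	2	3
AGG	g06	1	2	3	2	3
AGC	g06	1	2	3	2	3
CCA	g07	1	2	3	2	3
CCT	g07	1	2	3	2	3
CCG	g07	1	2	3	2	3
CCC	g07	1	2	3	2	3
ATA	g08	1	2	3	2	3
ATT	g08	1	2	3	2	3
ATG	g08	1	2	3	2	3
ATC	g08	1	2	3	2	3
CTA	g09	1	2	3	2	3
CTT	g09	1	2	3	2	3
CTG	g09	1	2	3	2	3
CTC	g09	1	2	3	2	3
TAA	g10	1	2	3	2	3
TAT	g10	1	2	3	2	3
TAG	g10	1	2	3	2	3
TAC	g10	1	2	3	2	3
GCA	g11	1	2	3	2	3
GCT	g11	1	2	3	2	3
GCG	g11	1	2	3	2	3
GCC	g11	1	2	3	2	3
TCG	g12	1	8	9	8	9
TCC	g12	1	8	9	8	9
TCA	g13	1	8	9	8	9
TCT	g13	1	8	9	8	9
TTA	g14	1	8	9	8	9
TTG	g14	1	8	9	8	9
TTT	g15	1	8	9	8	9
TTC	g15	1	8	9	8	9
TGT	g16	0.8648035	8	9	8	9
TGC	g16	0.8648035	8	9	8	9
TGA	g17	0.864803	8	9	8	9
TGG	g17	0.864803	8	9	8	9
GAT	g18	0.8344635	8	9	8	9
GAC	g18	0.8344635	8	9	8	9
GAA	g19	0.834463	8	9	8	9
GAG	g19	0.834463	8	9	8	9
GGG	g20	0.6446255	8	9	8	9
GGC	g20	0.6446255	8	9	8	9
GGA	g21	0.644625	8	9	8	9
GGT	g21	0.644625	8	9	8	9
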