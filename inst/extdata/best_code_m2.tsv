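codon	group	psi	phi_num	phi_den	phik_num	phik_den
CAT	g01	0.9867038	36	54	36	54
CAG	g01	0.9867038	36	54	36	54
CAC	g01	0.9867038	36	54	36	54
CTG	g01	0.9867038	36	54	36	54
CGG	g01	0.9867038	36	54	36	54
CCG	g01	0.9867038	36	54	36	54
CAA	g02	0.9866648	35	54	36	54
CTA	g02	0.9866648	35	54	36	54
CTT	g02	0.9866648	35	54	36	54
CTC	g02	0.9866648	35	54	36	54
CGA	g02	0.9866648	35	54	36	54
CCA	g02	0.9866648	35	54	36	54
GAG	g03	1	7	9	2	3
GAC	g03	1	7	9	2	3
GGC	g03	1	7	9	2	3
GCC	g03	1	7	9	2	3
GAA	g04	1	7	9	2	3
GGA	g04	1	7	9	2	3
GGG	g04	1	7	9	2	3
GCA	g04	1	7	9	2	3
GAT	g05	0.8262542	7	9	2	3
GTT	g05	0.8262542	7	9	2	3
GTG	g05	0.8262542	7	9	2	3
GCT	g05	0.8262542	7	9	2	3
GTA	g06	0.783784	34	36	2	3
GTC	g06	0.783784	34	36	2	3
GGT	g06	0.783784	34	36	2	3
GCG	g06	0.783784	34	36	2	3
ATC	g07	0.6426162	5	6	2	3
AGC	g07	0.6426162	5	6	2	3
ACC	g07	0.6426162	5	6	2	3
CCT	g07	0.6426162	5	6	2	3
ATT	g08	0.8457703	7	9	7	9
AGT	g08	0.8457703	7	9	7	9
ACT	g08	0.8457703	7	9	7	9
ATA	g09	0.813687	7	9	7	9
AGA	g09	0.813687	7	9	7	9
ACA	g09	0.813687	7	9	7	9
AAT	g10	0.7359857	23	27	7	9
AAG	g10	0.7359857	23	27	7	9
AGG	g10	0.7359857	23	27	7	9
AAA	g11	0.7170777	25	27	7	9
AAC	g11	0.7170777	25	27	7	9
CGC	g11	0.7170777	25	27	7	9
TAA	g12	0.5927813	23	27	7	9
TAC	g12	0.5927813	23	27	7	9
TTC	g12	0.5927813	23	27	7	9
TCT	g13	0.559873	25	27	7	9
TCG	g13	0.559873	25	27	7	9
CCC	g13	0.559873	25	27	7	9
TTA	g14	0.49327	25	27	7	9
TCA	g14	0.49327	25	27	7	9
CGT	g14	0.49327	25	27	7	9
ATG	g15	0.8650405	8	9	8	9
ACG	g15	0.8650405	8	9	8	9
TAT	g16	0.8027995	8	9	8	9
TAG	g16	0.8027995	8	9	8	9
TTT	g17	0.7850055	8	9	8	9
TGT	g17	0.7850055	8	9	8	9
TGC	g18	0.7838025	8	9	8	9
TCC	g18	0.7838025	8	9	8	9
TGA	g19	1	1	1	1	1
TTG	g20	0.996719	1	1	1	1
TGG	g21	0.573441	1	1	1	1
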