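codon	group	psi	phi_num	phi_den	phik_num	phik_den
AAG	g01	0.7453878	5	6	2	3
TAG	g01	0.7453878	5	6	2	3
TTC	g01	0.7453878	5	6	2	3
CAG	g01	0.7453878	5	6	2	3
ATC	g02	0.734763	8	9	2	3
TTA	g02	0.734763	8	9	2	3
GAA	g02	0.734763	8	9	2	3
GTA	g02	0.734763	8	9	2	3
ACG	g03	0.5928058	7	9	2	3
CCA	g03	0.5928058	7	9	2	3
CCT	g03	0.5928058	7	9	2	3
CCG	g03	0.5928058	7	9	2	3
AGC	g04	0.6837612	7	9	2	3
CAC	g04	0.6837612	7	9	2	3
CGC	g04	0.6837612	7	9	2	3
CCC	g04	0.6837612	7	9	2	3
GAG	g05	0.573447	7	9	2	3
GTG	g05	0.573447	7	9	2	3
GCA	g05	0.573447	7	9	2	3
GCG	g05	0.573447	7	9	2	3
ACT	g06	0.916417	7	9	7	9
TCT	g06	0.916417	7	9	7	9
GCT	g06	0.916417	7	9	7	9
AGG	g07	0.862386	7	9	7	9
TGG	g07	0.862386	7	9	7	9
CGG	g07	0.862386	7	9	7	9
TGC	g08	0.8267687	23	27	7	9
GTC	g08	0.8267687	23	27	7	9
GGC	g08	0.8267687	23	27	7	9
AGT	g09	0.8261313	7	9	7	9
TGT	g09	0.8261313	7	9	7	9
CGT	g09	0.8261313	7	9	7	9
ACC	g10	0.815771	25	27	7	9
TCC	g10	0.815771	25	27	7	9
GAC	g10	0.815771	25	27	7	9
ATG	g11	0.796867	7	9	7	9
TTG	g11	0.796867	7	9	7	9
CTG	g11	0.796867	7	9	7	9
GAT	g12	0.7812357	23	27	7	9
GGA	g12	0.7812357	23	27	7	9
GGT	g12	0.7812357	23	27	7	9
ATT	g13	0.774143	25	27	7	9
GTT	g13	0.774143	25	27	7	9
CAT	g13	0.774143	25	27	7	9
TTT	g14	0.7475287	23	27	7	9
CTT	g14	0.7475287	23	27	7	9
CTC	g14	0.7475287	23	27	7	9
AGA	g15	0.734763	7	9	7	9
TGA	g15	0.734763	7	9	7	9
CGA	g15	0.734763	7	9	7	9
ATA	g16	0.711267	23	27	7	9
CAA	g16	0.711267	23	27	7	9
CTA	g16	0.711267	23	27	7	9
TCG	g17	0.7241587	1	1	7	9
GGG	g17	0.7241587	1	1	7	9
GCC	g17	0.7241587	1	1	7	9
AAC	g18	1	8	9	8	9
TAC	g18	1	8	9	8	9
AAT	g19	1	8	9	8	9
TAT	g19	1	8	9	8	9
ACA	g20	1	8	9	8	9
TCA	g20	1	8	9	8	9
AAA	g21	1	8	9	8	9
TAA	g21	1	8	9	8	9
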