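group	phylum	class	order	family	genus	species
Annelida	1	2	4	7	12	16
Arthropoda	1	8	31	102	126	116
Ascomycota	1	3	2	4	2	3
Bacillariophyta	1	2	4	5	3	6
Basidiomycota	1	1	2	2	1	1
Bryozoa	1	1	1	1	1	1
Chordata	1	5	14	21	22	21
Ciliophora	1	1	1	1	1	1
Cnidaria	1	3	10	25	25	24
Discosea	1	1	3	4	6	18
Echinodermata	1	4	6	9	10	8
Evosea	1	1	1	1	2	2
Gastrotricha	1	0	1	1	1	1
Heterolobosea	1	0	0	1	1	0
Mollusca	1	2	10	24	28	26
Mucoromycota	1	1	1	1	1	0
Nematoda	1	1	2	3	3	2
Nemertea	1	2	2	2	2	2
Ochrophyta	1	3	9	17	41	66
Onychophora	1	1	1	2	2	2
Oomycota	1	2	4	5	12	96
Porifera	1	2	5	8	5	5
Rhodophyta	1	2	15	32	55	71
Rotifera	1	2	2	8	12	29
Streptophyta	1	1	2	2	2	1
Tubulinea	1	1	1	1	4	4
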