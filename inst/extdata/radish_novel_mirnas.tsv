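name	mature	size	precursor_length	mfe	reads_ck	reads_cd200	loci
miRn1	UCGCUUGGUGCAGGUCGGGAA	21	141	-72.20	8263	9468	1
miRn2	UGAAGCUGCCAGCAUGAUCUA	21	118	-48.00	1524	4358	1
miRn3	AAGCUAGAGACUUAAAACAAG	21	139	-23.95	65	8	1
miRn4	GCGUAUGAGGAGCCAAGCAUA	21	106	-49.30	1045	574	1
miRn5	GUGGUGACGGUGGUGGUGCGA	21	99	-36.40	5	0	2
miRn6	CAGGGAACAAGCAGAGCAUGG	21	110	-46.10	3972	2741	1
miRn7	AUAUACUGAAGUUUAUACUCU	21	208	-37.00	58	362	1
miRn8	GUAUGAGGAGCCAAGCAUAU	20	107	-46.60	1137	563	1
miRn9	GUACGACGAAGAUGAGCCGACA	22	110	-19.60	36	25	3
miRn10	UGGAGGCAGCGGUUCAUCGAUC	22	140	-45.70	378	452	1
miRn11	GCUCAAGAAAGCUGUGGGAAA	21	147	-39.04	0	242	1
miRn12	AAACUGCCUAAACAAACAUAUC	22	171	-40.44	56	38	1
miRn13	GCUGGAGGCAGCGGUUCAUCGAUC	24	142	-46.80	827	2326	1
miRn14	AGAUGACAGUGAGGCUUCUUA	21	108	-18.20	0	28	4
miRn15	CCCGCCUUGCAUCAACUGAAU	21	137	-66.30	222	34	1
miRn16	UCGCUUGGUGCAGGUCGGGAC	21	142	-73.60	12154	14602	1
miRn17	UUGGACUGAAGGGAGCUCCUU	21	201	-86.70	8	0	1
miRn18	CGCCUUGCAUCAACUGAAUCA	21	108	-56.70	1721	1423	1
miRn19	AUGGAUGUAUGAUAUGAUGGA	21	136	-41.40	0	21	1
miRn20	GGAAUGUUGUUUGGCUCGAAG	21	72	-20.00	10	27	1
miRn21	UCGGACCAGGCUUCAUUCCCC	21	133	-67.20	36853	53357	1
miRn22	AAGCUGCCAGCGUGAUCUUAAC	22	101	-41.80	2638	3280	1
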