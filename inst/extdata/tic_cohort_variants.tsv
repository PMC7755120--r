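# mt-tRNA variants detected in a 494-case tic-disorder cohort (485 controls).
# Input columns: position (rCRS), ref, alt (heavy strand; alt 'del' marks a
# single-base deletion), ci (reported interspecies conservation index, %),
# case_carriers, control_carriers, known (previously reported, Y/N).
# Trailing columns (gene, trna_position, location, wc_pair, wc_dir) are the
# reported structural annotations, kept for cross-checks; the pipeline
# recomputes them from coordinates alone.  Curation note: the source table
# listed tRNA position '98' for m.14693A>G; no cloverleaf position 98 exists
# and it is recorded here as 54 (T-loop, adjacent to m.14692 at 55).
position	ref	alt	ci	case_carriers	control_carriers	known	gene	trna_position	location	wc_pair	wc_dir
4373	T	C	100	1	0	N	MT-TQ	28	Anticodon stem	A-U	down
4452	T	C	100	1	0	Y	MT-TM	55	T-loop		
5558	A	G	100	2	0	Y	MT-TW	49	T-stem	A-U	down
5587	T	C	100	2	0	Y	MT-TA	73	ACC terminus		
5595	G	A	100	1	0	N	MT-TA	65	T-stem	C-G	down
5774	T	C	93	1	0	Y	MT-TC	59	T-loop		
5794	T	C	86	1	0	N	MT-TC	38	Anticodon loop		
5819	T	C	100	1	0	N	MT-TC	8	D-A junction		
7502	C	T	86	1	0	Y	MT-TS1	14	DHU-loop		
10055	A	G	100	2	0	N	MT-TG	70	ACC-stem	A-U	down
12141	A	G	82	1	0	N	MT-TH	4	ACC-stem	A-U	down
12279	A	G	100	2	0	N	MT-TL2	14	DHU-loop		
14692	A	G	88	1	0	N	MT-TE	55	T-loop		
15910	C	T	100	1	0	N	MT-TT	25	DHU-stem	C-G	down
15948	A	G	82	1	0	N	MT-TT	68	ACC-stem	A-U	down
15950	G	A	100	1	0	N	MT-TT	70	ACC-stem	G-C	down
15952	C	T	93	2	0	N	MT-TT	72	ACC-stem	C-G	down
15992	A	G	100	3	0	N	MT-TP	34	Anticodon loop		
593	T	C	29	2	2	Y	MT-TF	17	D-loop		
636	A	G	43	1	0	N	MT-TF	62	T-loop		
1607	T	C	59	1	0	N	MT-TV	6	ACC-stem	C-G	up
1664	G	A	29	1	1	Y	MT-TV	67	ACC-stem	A-U	up
3290	T	C	32	2	2	Y	MT-TL1	59	T-loop		
4363	T	C	79	1	3	Y	MT-TQ	38	AC loop		
4369	A	G	59	1	0	N	MT-TQ	32	Anticodon loop		
4385	A	G	68	1	1	N	MT-TQ	16	D-loop		
4386	T	C	46	7	13	Y	MT-TQ	15	D-loop		
4394	C	T	44	5	2	Y	MT-TQ	7	ACC-stem		
5567	T	C	65	1	0	Y	MT-TW	61	T-stem	U-A	down
5601	C	T	59	10	8	Y	MT-TA	59	T-loop		
5628	T	C	93	2	3	Y	MT-TA	31	Anticodon stem	U-A	down
5773	G	A	24	1	2	Y	MT-TC	61	T-loop		
5783	G	A	100	2	1	Y	MT-TC	50	T-stem	G-C	down
5786	T	C	50	1	0	Y	MT-TC	46	Variable loop		
5814	T	C	85	2	1	Y	MT-TC	13	D-stem	A-U	down
5821	G	A	65	13	10	Y	MT-TC	6	ACC-stem	G-C	down
5823	A	G	29	2	0	Y	MT-TC	4	ACC-stem	G-C	up
5836	A	G	83	1	2	Y	MT-TY	63	T-stem	G-C	up
5843	A	G	88	1	1	Y	MT-TY	54	T-loop		
5878	T	del	64	2	0	N	MT-TY	14	DHU-loop		
7492	C	T	68	1	1	Y	MT-TS1	27a	D-A junction	U-A	up
7572	T	C	29	1	2	N	MT-TD	60	T-loop		
8343	A	G	41	1	4	Y	MT-TK	54	T-loop		
9992	C	T	49	1	1	N	MT-TG	2	ACC-stem	C-G	down
10007	T	C	49	1	0	Y	MT-TG	19	D-loop		
10031	T	C	51	7	6	Y	MT-TG	44	Variable loop		
10410	T	C	12	2	4	Y	MT-TR	6	ACC-stem		
10411	A	G	41	1	0	Y	MT-TR	7	ACC-stem	A-U	down
10454	T	C	56	3	4	Y	MT-TR	55	T-loop		
10463	T	C	94	1	1	Y	MT-TR	67	ACC-stem		
12153	C	T	59	1	1	Y	MT-TH	16	D-loop		
12172	A	G	93	3	2	Y	MT-TH	38	AC loop		
12190	A	G	79	1	1	N	MT-TH	57	T-loop		
12192	G	A	12	3	1	N	MT-TH	59	T-loop		
12216	C	T	39	1	0	N	MT-TS2	10	D-loop		
12231	C	T	63	1	0	N	MT-TS2	39	Anticodon stem	A-U	up
12280	A	G	59	1	1	Y	MT-TL2	15	D-loop		
14687	A	G	93	1	1	Y	MT-TE	60	T-loop		
14693	A	G	98	10	7	Y	MT-TE	54	T-loop		
14696	A	G	93	1	1	Y	MT-TE	51	T-stem	G-C	up
14727	T	C	64	1	1	Y	MT-TE	16	DHU-loop		
15889	T	C	41	2	0	Y	MT-TT	2	ACC-stem	U-A	down
15900	T	C	73	1	1	Y	MT-TT	13	D-stem	U-A	down
15924	A	G	93	9	7	Y	MT-TT	39	ACC stem	A-U	down
15927	G	A	49	8	16	Y	MT-TT	42	ACC stem	G-C	down
15928	G	A	76	2	2	Y	MT-TT	43	ACC stem	G-C	down
15930	G	A	22	4	15	Y	MT-TT	45	Variable loop		
15932	T	C	64	3	0	Y	MT-TT	47	T-loop		
15937	A	G	50	1	0	Y	MT-TT	53	T-loop		
15940	T	C	24	4	3	Y	MT-TT	59	T-loop		
15951	A	G	68	1	4	Y	MT-TT	71	ACC-stem	A-U	down
15968	T	C	27	2	2	Y	MT-TP	61	T-stem	U-A	down
16000	G	T	19	1	1	Y	MT-TP	26	D-A junction	A-U	up
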