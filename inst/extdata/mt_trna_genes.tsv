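# Gene spans: rCRS NC_012920.1, 1-based inclusive.  Light-strand
# genes read 3'->5' in genomic coordinates (tRNA base = complement).
gene	amino_acid	start	end	strand
MT-TF	Phe	577	647	heavy
MT-TV	Val	1602	1670	heavy
MT-TL1	Leu(UUR)	3230	3304	heavy
MT-TI	Ile	4263	4328	heavy
MT-TQ	Gln	4329	4400	light
MT-TM	Met	4402	4469	heavy
MT-TW	Trp	5512	5579	heavy
MT-TA	Ala	5587	5655	light
MT-TN	Asn	5657	5729	light
MT-TC	Cys	5761	5826	light
MT-TY	Tyr	5827	5891	light
MT-TS1	Ser(UCN)	7446	7514	light
MT-TD	Asp	7518	7585	heavy
MT-TK	Lys	8295	8364	heavy
MT-TG	Gly	9991	10058	heavy
MT-TR	Arg	10405	10469	heavy
MT-TH	His	12138	12206	heavy
MT-TS2	Ser(AGY)	12207	12265	heavy
MT-TL2	Leu(CUN)	12266	12336	heavy
MT-TE	Glu	14674	14742	light
MT-TT	Thr	15888	15953	heavy
MT-TP	Pro	15956	16023	light
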