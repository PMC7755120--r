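# Tertiary (long-range) interaction partners per gene, conventional labels.
gene	pos1	pos2
MT-TF	8	14
MT-TF	18	55
MT-TF	19	56
MT-TF	26	44
MT-TF	54	58
MT-TV	8	14
MT-TV	18	55
MT-TV	19	56
MT-TV	26	44
MT-TV	54	58
MT-TL1	8	14
MT-TL1	15	48
MT-TL1	18	55
MT-TL1	19	56
MT-TL1	26	44
MT-TL1	54	58
MT-TI	8	14
MT-TI	15	48
MT-TI	18	55
MT-TI	19	56
MT-TI	26	44
MT-TI	54	58
MT-TQ	8	14
MT-TQ	15	48
MT-TQ	18	55
MT-TQ	19	56
MT-TQ	26	44
MT-TQ	54	58
MT-TM	8	14
MT-TM	15	48
MT-TM	18	55
MT-TM	19	56
MT-TM	26	44
MT-TW	8	14
MT-TW	15	48
MT-TW	18	55
MT-TW	26	44
MT-TA	8	14
MT-TA	15	48
MT-TA	18	55
MT-TA	19	56
MT-TA	26	44
MT-TA	54	58
MT-TN	8	14
MT-TN	15	48
MT-TN	18	55
MT-TN	19	56
MT-TN	26	44
MT-TN	54	58
MT-TC	8	14
MT-TC	18	55
MT-TC	19	56
MT-TC	26	44
MT-TC	54	58
MT-TY	8	14
MT-TY	15	48
MT-TY	18	55
MT-TY	26	44
MT-TY	54	58
MT-TS1	8	14
MT-TS1	15	48
MT-TS1	18	55
MT-TS1	19	56
MT-TS1	26	44
MT-TS1	54	58
MT-TD	8	14
MT-TD	15	48
MT-TD	18	55
MT-TD	19	56
MT-TD	26	44
MT-TD	54	58
MT-TK	8	14
MT-TK	15	48
MT-TK	18	55
MT-TK	19	56
MT-TK	26	44
MT-TK	54	58
MT-TG	8	14
MT-TG	15	48
MT-TG	18	55
MT-TG	26	44
MT-TG	54	58
MT-TR	8	14
MT-TR	15	48
MT-TR	18	55
MT-TR	26	44
MT-TH	8	14
MT-TH	15	48
MT-TH	18	55
MT-TH	19	56
MT-TH	26	44
MT-TH	54	58
MT-TS2	8	14
MT-TS2	15	48
MT-TS2	54	58
MT-TL2	8	14
MT-TL2	18	55
MT-TL2	19	56
MT-TL2	26	44
MT-TL2	54	58
MT-TE	8	14
MT-TE	15	48
MT-TE	18	55
MT-TE	19	56
MT-TE	26	44
MT-TE	54	58
MT-TT	8	14
MT-TT	26	44
MT-TP	8	14
MT-TP	18	55
MT-TP	19	56
MT-TP	26	44
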