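#per-sample variant-concordance counts of six samples against the Sanger truth panel
#platform PGM: Torrent Suite 4.2 calls; platform MiSeq: GATK-pipeline calls
#n_truth: Sanger truth variants; n_detected: truth variants found; n_fn: false negatives; n_extra: calls absent from truth
sample	platform	dataset	n_truth	n_detected	n_fn	n_extra
1	PGM	IonShear	33	32	1	1
1	PGM	Covaris	33	32	1	1
1	PGM	NEBNext	33	32	1	1
1	MiSeq	Covaris	33	33	0	1
1	MiSeq	NEBNext	33	33	0	1
1	MiSeq	NexteraXT	33	33	0	1
2	PGM	IonShear	13	11	2	1
2	PGM	Covaris	13	12	1	1
2	PGM	NEBNext	13	12	1	1
2	MiSeq	Covaris	13	13	0	1
2	MiSeq	NEBNext	13	13	0	1
2	MiSeq	NexteraXT	13	13	0	1
4	PGM	IonShear	33	32	1	0
4	PGM	Covaris	33	31	2	0
4	PGM	NEBNext	33	31	2	0
4	MiSeq	Covaris	33	33	0	0
4	MiSeq	NEBNext	33	33	0	0
4	MiSeq	NexteraXT	33	33	0	0
9	PGM	IonShear	36	35	1	2
9	PGM	Covaris	36	35	1	2
9	PGM	NEBNext	36	35	1	2
9	MiSeq	Covaris	36	36	0	3
9	MiSeq	NEBNext	36	36	0	2
9	MiSeq	NexteraXT	36	36	0	2
14	PGM	IonShear	57	56	1	0
14	PGM	Covaris	57	56	1	0
14	PGM	NEBNext	57	56	1	0
14	MiSeq	Covaris	57	57	0	1
14	MiSeq	NEBNext	57	57	0	1
14	MiSeq	NexteraXT	57	57	0	0
21	PGM	IonShear	42	40	2	0
21	PGM	Covaris	42	41	1	0
21	PGM	NEBNext	42	41	1	0
21	MiSeq	Covaris	42	41	1	0
21	MiSeq	NEBNext	42	41	1	0
21	MiSeq	NexteraXT	42	41	1	0
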