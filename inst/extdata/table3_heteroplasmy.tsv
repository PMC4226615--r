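#minor-allele fractions (percent) of heteroplasmic variants, one row per sequencing method
#PGM methods: IonShear, Covaris, NEBNext shearing; MiSeq methods: Covaris, NEBNext, NexteraXT preparations
sample	variant	platform	method	fraction
1	m.12071T>C	PGM	IonShear	12.2
1	m.12071T>C	PGM	Covaris	12.2
1	m.12071T>C	PGM	NEBNext	12.1
1	m.12071T>C	MiSeq	Covaris	12
1	m.12071T>C	MiSeq	NEBNext	12
1	m.12071T>C	MiSeq	NexteraXT	23
2	m.7989T>C	PGM	IonShear	17.1
2	m.7989T>C	PGM	Covaris	14.7
2	m.7989T>C	PGM	NEBNext	14.1
2	m.7989T>C	MiSeq	Covaris	19
2	m.7989T>C	MiSeq	NEBNext	19
2	m.7989T>C	MiSeq	NexteraXT	13
9	m.9769T>C	PGM	IonShear	9.7
9	m.9769T>C	PGM	Covaris	9
9	m.9769T>C	PGM	NEBNext	8.5
9	m.9769T>C	MiSeq	Covaris	8
9	m.9769T>C	MiSeq	NEBNext	8
9	m.9769T>C	MiSeq	NexteraXT	8
9	m.10866T>C	PGM	IonShear	7.3
9	m.10866T>C	PGM	Covaris	6
9	m.10866T>C	PGM	NEBNext	6.4
9	m.10866T>C	MiSeq	Covaris	7
9	m.10866T>C	MiSeq	NEBNext	9
9	m.10866T>C	MiSeq	NexteraXT	7
9	m.8207C>T	PGM	IonShear	1.5
9	m.8207C>T	PGM	Covaris	1.3
9	m.8207C>T	PGM	NEBNext	1.5
9	m.8207C>T	MiSeq	Covaris	2
9	m.8207C>T	MiSeq	NEBNext	1
9	m.8207C>T	MiSeq	NexteraXT	2
14	m.5609T>C	PGM	IonShear	4
14	m.5609T>C	PGM	Covaris	8
14	m.5609T>C	PGM	NEBNext	4.8
14	m.5609T>C	MiSeq	Covaris	4
14	m.5609T>C	MiSeq	NEBNext	4
14	m.5609T>C	MiSeq	NexteraXT	4
14	m.7453G>A	PGM	IonShear	52
14	m.7453G>A	PGM	Covaris	55
14	m.7453G>A	PGM	NEBNext	53
14	m.7453G>A	MiSeq	Covaris	53
14	m.7453G>A	MiSeq	NEBNext	54
14	m.7453G>A	MiSeq	NexteraXT	56
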