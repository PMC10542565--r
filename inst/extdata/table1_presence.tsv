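chrom	pos	ref	alt	gene	effect	N2	CC1	PY12237	PY12265	PY12270	PY12272
IV	565523	A	G	efn-4	missense	0	0	1	0	0	1
III	8921065	A	C	ZK637.15	missense	0	0	1	0	1	0
III	11887252	C	T	faah-5	missense	0	0	1	0	1	0
IV	1875890	AGACTATGGAGATAAGGAACGTTTGGCTCAAGT	TCCCT	egl-4	indel	0	0	1	0	1	0
IV	3336613	C	T	F42A6.6	missense	0	0	1	0	1	0
V	6819161	A	C	dmsr-13	missense	0	0	1	0	1	0
V	12055146	TC	GT	F10C2.7	missense	0	0	1	0	1	0
V	15939563	A	G	srw-55	missense	0	0	1	0	1	0
V	20064174	T	C	ttx-1	missense	0	0	1	0	1	0
X	8245825	C	T	kqt-2	missense	0	0	1	0	1	0
X	14899594	G	A	lips-8	missense	0	0	1	0	1	0
X	15966176	A	C	pqn-11	missense	0	0	1	0	1	0
X	16269688	C	T	ifa-3	missense	0	0	1	0	1	0
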