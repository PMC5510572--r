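pedigree_id	pedigree_label	phenotype_class	status	sex	age_onset	age_diagnosis	tumor_size	diagnosis
1	UK FIPA 1	GH	affected	M	11	15	Hyperplasia	Gigantism
1	UK FIPA 1	GH	affected	M	15	26	Macro	Gigantism
1	UK FIPA 1	GH	affected	M	27.5	29	Macro	Acromegaly
1	UK FIPA 1	GH	affected	M	na	47	Micro	Acromegaly (prospective), GIST
1	UK FIPA 1	GH	unaffected_carrier	F	na	6	na	na
1	UK FIPA 1	GH	unaffected_carrier	F	na	34	na	na
1	UK FIPA 1	GH	unaffected_carrier	M	na	34	na	na
1	UK FIPA 1	GH	unaffected_carrier	F	na	58	na	na
2	UK FIPA 2	GH	affected	M	22	23	Macro	Gigantism
2	UK FIPA 2	GH	affected	F	24	28	nk	Acromegaly
2	UK FIPA 2	GH	unaffected_carrier	F	na	32	na	na
2	UK FIPA 2	GH	unaffected_carrier	M	na	71	na	na
3	US FIPA 1	GH/NFPA	affected	F	22	23	Macro	NFPA (silent GH pos)
3	US FIPA 1	GH/NFPA	affected	M	25	26	Macro	Acromegaly (apoplexy)
3	US FIPA 1	GH/NFPA	unaffected_carrier	F	na	55	na	obligate carrier
4	US FIPA 2	GH/NFPA	affected	M	17	17	Macro	Gigantism
4	US FIPA 2	GH/NFPA	affected	F	12	13	Macro	Gigantism
4	US FIPA 2	GH/NFPA	affected	F	34	40	Macro	NFPA
4	US FIPA 2	GH/NFPA	unaffected_carrier	F	na	60	na	obligate carrier
5	France Simplex	GH	affected	M	9	14	Macro	Gigantism, psychosis
6	UK Simplex 1	GH	affected	M	20	21	Macro	Gigantism
7	UK Simplex 2	GH	affected	M	13	18	Macro	Gigantism
8	US Simplex	GH	affected	M	17	17	Macro	Gigantism
9	UK Simplex 3	GH	affected	M	18	23	Macro	Acromegaly
9	UK Simplex 3	GH	unaffected_carrier	F	na	66	na	na
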