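clade_id	stability	rnai_phenotype	oenocyte_expression
CG1443	stable	Lethal	N
CG4020	stable	Lethal	Yes (female)
CG4770	stable	Lethal	N
CG5065	stable	Lethal	N
CG8303	stable	Lethal	N
CG8306	stable	Lethal	N
CG10096	stable	Lethal	N
CG12268	stable	Lethal	N
CG34342	stable	Lethal	N
CG1441	stable	Viable	N
CG18031	stable	Viable	N
CG30427	stable	Viable	N
CG10097	unstable	Viable	Yes (male)
CG13091	unstable	Viable	Yes (male)
CG14893	unstable	Viable	N
CG17562	unstable	Viable	N
CG17560	unstable	Lethal	Yes (both)
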