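label	lnL_null	lnL_alt	df	p0	p1	p2a	p2b	omega0	omega1	omega2
DanaGF17060	-11225.209	-11219.17	1	0.744	0.167	0.073	0.016	0.124	1	11.202
DanaGF17063	-11226.499	-11223.058	1	0.762	0.174	0.051	0.012	0.126	1	14.503
DsecGM26015	-4554.441	-4529.358	1	0.8	0.146	0.045	0.009	0.117	1	257.742
DperGL27182/DpseGA32357	-4569.562	-4565.092	1	0.815	0.147	0.032	0.006	0.125	1	13.669
DvirGJ21443	-14488.933	-14480.535	1	0.682	0.256	0.045	0.017	0.144	1	15.825
DvirGJ22672/22673/26512	-14491.793	-14488.424	1	0.703	0.267	0.022	0.008	0.144	1	8.945
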