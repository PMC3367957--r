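label	Asellus	Cloeon	Culex	Daphnia	Chironomus	Lymnaea	Rana
Asellus	1	0.56	0.59	0.41	0.79	0.44	0.83
Cloeon	0.56	1	0.75	0.39	0.51	0.22	0.47
Culex	0.59	0.75	1	0.78	0.73	0.27	0.44
Daphnia	0.41	0.39	0.78	1	0.64	0.13	0.17
Chironomus	0.79	0.51	0.73	0.64	1	0.36	0.67
Lymnaea	0.44	0.22	0.27	0.13	0.36	1	0.43
Rana	0.83	0.47	0.44	0.17	0.67	0.43	1
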