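label	Hydaticus(A)	Acilius(L2)	Acilius(L3)	Acilius(A)	Dytiscus(L3)	Dytiscus(A)	Ilyocoris(A)	Notonecta(A)	Coenagrion(F-0)	Libellula(F-2)	Libellula(F-0)	Sympetrum(F-0)	Anax(F-0)
Hydaticus(A)	1	0.09	0.3	0.94	0.59	0.78	0.78	0.21	0.14	0.89	0.76	0.72	0.56
Acilius(L2)	0.09	1	0.89	0.41	0.21	0.21	0.26	0.97	0.88	0.5	0.69	0.74	0.72
Acilius(L3)	0.3	0.89	1	0.55	0.35	0.35	0.39	0.87	0.66	0.57	0.78	0.77	0.81
Acilius(A)	0.94	0.41	0.55	1	0.64	0.8	0.79	0.52	0.41	0.98	0.93	0.91	0.76
Dytiscus(L3)	0.59	0.21	0.35	0.64	1	0.92	0.82	0.28	0.17	0.58	0.61	0.59	0.8
Dytiscus(A)	0.78	0.21	0.35	0.8	0.92	1	0.95	0.3	0.22	0.76	0.72	0.71	0.78
Ilyocoris(A)	0.78	0.26	0.39	0.79	0.82	0.95	1	0.34	0.27	0.78	0.73	0.73	0.74
Notonecta(A)	0.21	0.97	0.87	0.52	0.28	0.3	0.34	1	0.8	0.57	0.79	0.82	0.78
Coenagrion(F-0)	0.14	0.88	0.66	0.41	0.17	0.22	0.27	0.8	1	0.57	0.58	0.67	0.57
Libellula(F-2)	0.89	0.5	0.57	0.98	0.58	0.76	0.78	0.57	0.57	1	0.91	0.92	0.74
Libellula(F-0)	0.76	0.69	0.78	0.93	0.61	0.72	0.73	0.79	0.58	0.91	1	0.99	0.9
Sympetrum(F-0)	0.72	0.74	0.77	0.91	0.59	0.71	0.73	0.82	0.67	0.92	0.99	1	0.89
Anax(F-0)	0.56	0.72	0.81	0.76	0.8	0.78	0.74	0.78	0.57	0.74	0.9	0.89	1
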