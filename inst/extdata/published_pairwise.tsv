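disorder1	disorder2	r	df	se	p	p_bonf	p_perm	p_perm_censored
BD	SCZ	0.81	73	0.068	1.13e-18	2.38e-17	1e-04	TRUE
BD	MDD	0.69	73	0.085	1.21e-11	2.55e-10	1e-04	TRUE
OCD	SCZ	0.65	72	0.09	5.53e-10	1.16e-08	1e-04	TRUE
MDD	SCZ	0.58	73	0.095	5.55e-08	1.17e-06	1e-04	TRUE
ADHD	BD	-0.53	73	0.099	1.18e-06	2.48e-05	1e-04	TRUE
BD	OCD	0.5	72	0.102	4.74e-06	9.95e-05	1e-04	TRUE
MDD	OCD	0.46	72	0.104	3.28e-05	6.89e-04	1e-04	TRUE
ASD	BD	0.38	73	0.108	8.98e-04	0.02	1e-04	TRUE
ASD	SCZ	0.36	73	0.109	1.35e-03	0.03	0.0176	FALSE
ADHD	MDD	-0.33	73	0.111	4.27e-03	0.09	0.019	FALSE
ADHD	SCZ	-0.32	73	0.111	4.63e-03	0.1	0.0014	FALSE
Epilepsy	MDD	-0.37	39	0.149	0.02	0.38	0.0056	FALSE
ADHD	Epilepsy	-0.36	39	0.149	0.02	0.41	0.004	FALSE
ASD	MDD	0.26	73	0.113	0.02	0.46	0.024	FALSE
Epilepsy	OCD	-0.19	39	0.157	0.23	1	0.22	FALSE
BD	Epilepsy	0.17	39	0.158	0.3	1	0.3	FALSE
ADHD	OCD	-0.1	72	0.117	0.39	1	0.39	FALSE
ADHD	ASD	-0.06	73	0.117	0.6	1	0.6	FALSE
Epilepsy	SCZ	-0.03	39	0.16	0.86	1	0.85	FALSE
ASD	Epilepsy	0.02	39	0.16	0.91	1	0.91	FALSE
ASD	OCD	0	72	0.118	0.97	1	0.97	FALSE
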