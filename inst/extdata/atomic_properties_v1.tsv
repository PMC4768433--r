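element	mass	vdw_radius	polarizability	electronegativity	refractivity	hardness	logp_contrib	psa_contrib
H	1.008	1.20	0.667	2.20	1.02	6.43	0.23	0.00
B	10.811	1.92	3.030	2.04	3.95	4.01	0.20	0.00
C	12.011	1.70	1.760	2.55	2.42	5.00	0.08	0.00
N	14.007	1.55	1.100	3.04	2.62	7.23	-0.60	11.68
O	15.999	1.52	0.802	3.44	1.64	6.08	-0.47	9.23
F	18.998	1.47	0.557	3.98	0.92	7.01	0.22	0.00
Si	28.086	2.10	5.380	1.90	7.00	3.38	0.50	0.00
P	30.974	1.80	3.630	2.19	8.74	4.88	-0.50	13.59
S	32.060	1.80	2.900	2.58	7.69	4.14	0.25	25.30
Cl	35.453	1.75	2.180	3.16	5.84	4.68	0.65	0.00
Br	79.904	1.85	3.050	2.96	8.74	4.22	0.86	0.00
I	126.904	1.98	5.350	2.66	13.90	3.69	1.12	0.00
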