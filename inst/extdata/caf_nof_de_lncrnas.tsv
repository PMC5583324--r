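symbol	logFC	p	adj_p
ARHGEF26-AS1	-1.209	1.82E-05	5.22E-04
CASC2	-1.751	3.74E-12	1.86E-08
DLEU2	-1.539	1.51E-07	2.30E-05
FAM106A	-1.446	2.00E-05	5.54E-04
FLJ39739	1.297	1.12E-03	7.90E-03
FLJ22763	-1.142	5.47E-08	1.16E-05
FLJ42627	-1.382	1.04E-04	1.63E-03
FLJ45340	-1.613	2.51E-05	6.43E-04
GAS5	2.09	2.82E-05	6.96E-04
H19	2.377	5.95E-03	2.46E-02
HCG18	-1.826	1.44E-08	4.58E-06
HYMAI	-1.12	8.71E-05	1.46E-03
LINC00152	2.161	8.75E-05	1.46E-03
LINC00276	-1.284	2.20E-10	2.93E-07
LINC00461	-1.7	9.98E-08	1.75E-05
LINC00621	1.213	5.81E-03	2.41E-02
LOC100133669	-1.028	4.89E-05	1.00E-03
LOC100190938	-2.25	7.88E-06	2.96E-04
LOC100240734	-1.019	5.13E-08	1.13E-05
LOC100272216	-1.803	9.46E-04	7.07E-03
LOC100499466	1.22	1.71E-04	2.28E-03
LOC100506013	1.226	7.05E-03	2.76E-02
LOC100506710	1.367	2.21E-03	1.25E-02
LOC284454	1.16	2.00E-03	1.17E-02
LOC285084	-1.456	3.56E-06	1.78E-04
LOC285696	-1.413	2.94E-06	1.56E-04
LOC339988	-1.107	2.57E-03	1.39E-02
LOC388692	-1.048	1.87E-06	1.14E-04
LOC389634	-1.134	5.54E-07	5.04E-05
LOC642852	1.011	1.69E-03	1.05E-02
MALAT1	1.244	2.83E-02	7.40E-02
MEG3	1.09	3.66E-02	8.93E-02
MIR100HG	1.347	5.28E-03	2.26E-02
MIR22HG	1.846	2.38E-04	2.85E-03
NEAT1	1.297	4.94E-03	1.88E-02
PGM5-AS1	-2.305	1.28E-06	8.91E-05
TUG1	1.801	3.95E-04	3.98E-03
XIST	1.439	1.19E-03	7.32E-03
ZNRD1-AS1	-1.415	2.84E-09	1.48E-06
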