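phylum	N	p_sys	sqrtn_sys	prod_sys	n_2010_GM_SE	p_2010_GM_SE	sqrtn_2010_GM_SE	prod_2010_GM_SE	n_2011_GM_SE	p_2011_GM_SE	sqrtn_2011_GM_SE	prod_2011_GM_SE	n_2012_GM_SE	p_2012_GM_SE	sqrtn_2012_GM_SE	prod_2012_GM_SE
Actinobacteria	8	1	2.8284271	2.83	1	0.13	1	0.13	6	0.75	2.44948974	1.84	1	0.13	1	0.13
Spirochaetes	7	1	2.6457513	2.65	2	0.29	1.414213562	0.41	6	0.86	2.44948974	2.11	3	0.43	1.732051	0.74
Bacteroidetes	387	1	19.672316	19.67	207	0.54	14.38749457	7.77	206	0.53	14.3527001	7.61	85	0.22	9.219544	2.03
Proteobacteria	1429	1	37.802116	37.8	768	0.54	27.71281292	14.96	492	0.35	22.181073	7.76	716	0.5	26.75818	13.38
Cyanobacteria	24	1	4.8989795	4.9	24	1	4.898979486	4.9	1	0.04	1	0.04	6	0.25	2.44949	0.61
Nitrospira	18	1	4.2426407	4.24	1	0.06	1	0.06	18	1	4.24264069	4.24	0	0	0	0
Acidobacteria	11	1	3.3166248	3.32	1	0.09	1	0.09	10	0.91	3.16227766	2.88	2	0.18	1.414214	0.25
Aquificae	2	1	1.4142136	1.41	1	0.5	1	0.5	1	0.5	1	0.5	0	0	0	0
Deinococcus-Thermus	154	1	12.409674	12.41	6	0.04	2.449489743	0.1	154	1	12.4096736	12.41	5	0.03	2.236068	0.07
Firmicutes	7	1	2.6457513	2.65	0	0	0	0	3	0.43	1.73205081	0.74	5	0.71	2.236068	1.59
Chloroflexi	8	1	2.8284271	2.83	0	0	0	0	7	0.88	2.64575131	2.33	1	0.13	1	0.13
Armatimonadetes	2	1	1.4142136	1.41	0	0	0	0	1	0.5	1	0.5	1	0.5	1	0.5
Verrucomicrobia	3	1	1.7320508	1.73	0	0	0	0	3	1	1.73205081	1.73	1	0.33	1	0.33
TM7	1	1	1	1	0	0	0	0	1	1	1	1	0	0	0	0
WS3	1	1	1	1	0	0	0	0	1	1	1	1	0	0	0	0
Gemmatimonadetes	1	1	1	1	0	0	0	0	1	1	1	1	0	0	0	0
Unclassified Bacteria	944	1	1	1	467	0.49	21.61018278	10.59	337	0.36	18.3575598	6.61	394	0.42	19.84943	8.34
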