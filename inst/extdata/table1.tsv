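variable	unit	2010_GM_PC	2010_GM_SE	2011_GM_SE	2012_GM_PC	2012_GM_SE
Temperature	degC	75	65	60	75	65
pH	pH	7.5	7.25	6.75	7.75	7.0
TDS	g/l	1	0.7	0.3	0.8	0.5
Sulfate	mM	2.5	2.1	3.2	3	2.5
Sulfide	uM	232	290	170	155	203
Thiosulfate	mM	5	4.2	2.6	4.5	3.7
Ferric	uM	50	20	10	40	20
Ferrous	mM	6.0	4.8	1.2	5.0	2.5
Acetate	uM	15	12	5	15	15
Formate	uM	20	15	5	15	10
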