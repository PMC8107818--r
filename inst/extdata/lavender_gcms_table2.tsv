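compound_id	name	cas	retention_time_min	retention_index	pct_total
cmp01	Beta-myrcene		6.1048	996.5813	9.642
cmp02	3-Carene		7.1052	1037.5394	7.549
cmp03	Beta-ocimene		7.5053	1053.9201	6.203
cmp04	Linalool		9.0309	1119.3528	21.999
cmp05	1-Octen-3-yl-acetate		9.0725	1121.3650	1.254
cmp06	2,4,6-Octatriene, 3,4-dimethyl-		9.4144	1137.9026	4.91
cmp07	2,4,6-Octatriene, 2,6-dimethyl-, (E,Z)-		9.6728	1150.4014	0.746
cmp08	4-Hexen-1-ol, 5-methyl-2-(1-methylethenyl)-, (R)-		10.2980	1180.6423	2.198
cmp09	3-Cyclohexen-1-ol, 4-methyl-1-(1-methylethyl)-, (R)-		10.5565	1193.1459	5.981
cmp10	Butanoic acid, hexyl ester		10.6231	1196.3674	1.057
cmp11	Alpha-terpineol		10.8399	1208.1718	2.426
cmp12	Tricyclo [2.2.1.0 (2,6)]heptane, 1,3,3-trimethyl-		11.9070	1269.7116	16.095
cmp13	4-Hexen-1-ol, 5-methyl-2-(1-methylethenyl)-, acetate		12.3905	1297.5951	4.334
cmp14	2,6-Octadien-1-ol, 3,7-dimethyl-, acetate, (Z)-		13.5159	1371.7777	2.155
cmp15	Geranyl acetate		13.8077	1391.1047	3.097
cmp16	Tricyclo [2.2.1.0 (2,6)]heptane, 1,7-dimethyl-7-(4-methyl-3-pentenyl)-, (-)-		14.3912	1433.1223	0.995
cmp17	Caryophyllene		14.4663	1438.6489	4.627
cmp18	(E)-beta-farnesene		14.8247	1465.0231	3.94
cmp19	Caryophyllene oxide		16.6587	1608.6612	0.792
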