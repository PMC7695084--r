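district	eu	year	survey_cost_usd	population	mda_cost_usd	tf_category
Nkasi	Nkasi	2018	8719.32	318958	28884.11	<5
Kalambo	Kalambo	2018	7610.23	235589	21351.88	5-9.9
Ngara	Ngara	2018	9501.14	386638	16728.38	<5
Songwe	Songwe	2018	6546.59	153820	10947.88	5-9.9
Chunya	Chunya	2018	8673.86	163315	12595.67	<5
Bahi	Bahi	2018	6382.95	251080	22565.15	<5
Chemba	Chemba	2018	8401.14	267014	32301.05	5-9.9
Liwale	Liwale	2018	7610.23	96427	18195.65	<5
Longido	Longido	2018	10616.59	144410	18468.33	5-9.9
Monduli	Monduli	2018	10616.59	186477	20565.78	<5
Ngorongoro	Ngorongoro	2018	11611.66	204487	24463.96	10-29.9
Kalambo	Kalambo	2017	10341.64	235589	26436.67	5-9.9
Kilindi	Kilindi	2017	8788.41	258372	26248.10	<5
Itigi	Itigi	2017	8427.59	127680	14067.43	<5
Manyoni	Manyoni	2017	8597.45	213010	20933.81	<5
Kongwa	Kongwa south	2017	6973.86	197409	23779.53	<5
Kongwa	Kongwa north	2017	8835.14	113042		<5
Chamwino	Chamwino south	2017	8256.36	155647	39564.67	<5
Chamwino	Chamwino north	2017	8487.73	147574		<5
Meatu	Meatu	2017	8821.82	321781	31622.54	<5
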