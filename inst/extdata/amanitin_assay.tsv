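species	group	larvae_per_vial	surv_control	surv_toxin	chisq	p_printed
cardinoides	Cardini	20	0.18	0.08	4.5	.0339
parthenogenetica	Cardini	15	0.417	0.0667	21.78	<.0001
arawakana	Cardini	25	0.328	0	63.95	<.0001
dunni	Cardini	20	0.48	0	80.97	<.0001
nigrodunni	Cardini	20	0.425	0.0125	48.08	<.0001
similis	Cardini	25	0.267	0	29.829	<.0001
funebris	Funebris	15	0.517	0	53.017	<.0001
macrospina	Funebris	15	0.293	0.187	2.35	.125
multispina	Funebris	15	0.433	0	20.696	<.0001
guarani	Guarani	15	0.4	0.24	4.44	.351
subbadia	Guarani	15	0.827	0.627	7.68	.00558
sulfurigaster	Immigrans	20	0.5	0	68.06	<.0001
pallidipennis	Pallidipennis	15	0.267	0	23.669	<.0001
occidentalis	Quinaria	20	0.43	0.33	2.13	.144
suboccidentalis	Quinaria	20	0.24	0.34	2.43	.119
tenebrosa	Quinaria	15	0.16	0.187	0.17	.68
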