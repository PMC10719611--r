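species	group	state
bizonata	Bizonata	NT
cardini	Cardini	A
cardinoides	Cardini	B
parthenogenetica	Cardini	B
polymorpha	Cardini	NT
acutilabella	Cardini	A
arawakana	Cardini	B
dunni	Cardini	B
nigrodunni	Cardini	B
similis	Cardini	B
funebris	Funebris	B
macrospina	Funebris	A
multispina	Funebris	B
guarani	Guarani	A
subbadia	Guarani	A
immigrans	Immigrans	B
quadrilineata	Immigrans	NT
albomicans	Immigrans	B
sulfurigaster	Immigrans	B
pruinosa	IncertaeSedis	NT
macroptera	Macroptera	NT
pallidipennis	Pallidipennis	B
angularis	Quinaria	A
brachynephros	Quinaria	A
deflecta	Quinaria	B
falleni	Quinaria	A
guttifera	Quinaria	A
innubila	Quinaria	NT
munda	Quinaria	NT
nigromaculata	Quinaria	A
occidentalis	Quinaria	A
palustris	Quinaria	B
phalerata	Quinaria	A
quinaria	Quinaria	B
recens	Quinaria	A
suboccidentalis	Quinaria	A
subpalustris	Quinaria	B
subquinaria_coastal	Quinaria	A
subquinaria_inland	Quinaria	A
tenebrosa	Quinaria	A
transversa	Quinaria	NT
grimshawi	Repleta	NT
neotestacea	Testacea	NT
orientacea	Testacea	NT
putrida	Testacea	A
testacea	Testacea	NT
tripunctata	Tripunctata	A
virilis	Virilis	NT
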