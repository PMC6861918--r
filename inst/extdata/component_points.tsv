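compound	component	points
desmethylclomipramine	concordance_acute	0
desmethylclomipramine	concordance_chronic	3
desmethylclomipramine	bbb	5
desmethylclomipramine	water_solubility	5
desmethylclomipramine	tnfa	2
desmethylclomipramine	nitrite	1
desmethylclomipramine	viability	0
desmethylclomipramine	engagement_Nfe2l2_inflammatory	1
desmethylclomipramine	engagement_Gclm_inflammatory	0
desmethylclomipramine	engagement_Hmox1_inflammatory	0
desmethylclomipramine	engagement_Nqo1_inflammatory	0
desmethylclomipramine	engagement_Nfe2l2_non_inflammatory	1
desmethylclomipramine	engagement_Gclm_non_inflammatory	0
desmethylclomipramine	engagement_Hmox1_non_inflammatory	0
desmethylclomipramine	engagement_Nqo1_non_inflammatory	0
ionomycin	concordance_acute	3
ionomycin	concordance_chronic	3
ionomycin	bbb	-5
ionomycin	water_solubility	0
ionomycin	tnfa	2
ionomycin	nitrite	1
ionomycin	viability	0
ionomycin	engagement_Nfe2l2_inflammatory	0
ionomycin	engagement_Gclm_inflammatory	0
ionomycin	engagement_Hmox1_inflammatory	0
ionomycin	engagement_Nqo1_inflammatory	1
ionomycin	engagement_Nfe2l2_non_inflammatory	0
ionomycin	engagement_Gclm_non_inflammatory	0
ionomycin	engagement_Hmox1_non_inflammatory	0
ionomycin	engagement_Nqo1_non_inflammatory	0
trimipramine	concordance_acute	0
trimipramine	concordance_chronic	0
trimipramine	bbb	5
trimipramine	water_solubility	5
trimipramine	tnfa	2
trimipramine	nitrite	1
trimipramine	viability	0
sirolimus	concordance_acute	0
sirolimus	concordance_chronic	0
sirolimus	bbb	5
sirolimus	water_solubility	5
sirolimus	tnfa	2
sirolimus	nitrite	2
sirolimus	viability	1
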