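compound	gene	condition	log2fc	p
desmethylclomipramine	Nfe2l2	inflammatory	0.282	1.87e-2
desmethylclomipramine	Gclm	inflammatory	0.099	7.70e-1
desmethylclomipramine	Hmox1	inflammatory	0.039	7.85e-1
desmethylclomipramine	Nqo1	inflammatory	-0.056	6.64e-1
desmethylclomipramine	Nfe2l2	non_inflammatory	0.200	3.83e-2
desmethylclomipramine	Gclm	non_inflammatory	0.118	7.83e-1
desmethylclomipramine	Hmox1	non_inflammatory	0.050	3.98e-1
desmethylclomipramine	Nqo1	non_inflammatory	NA	1.09e-1
ionomycin	Nfe2l2	inflammatory	-0.052	7.87e-1
ionomycin	Gclm	inflammatory	0.262	1.04e-1
ionomycin	Hmox1	inflammatory	0.298	1.54e-1
ionomycin	Nqo1	inflammatory	0.565	8.72e-3
ionomycin	Nfe2l2	non_inflammatory	0.125	1.65e-1
ionomycin	Gclm	non_inflammatory	0.388	4.52e-1
ionomycin	Hmox1	non_inflammatory	0.281	6.58e-2
ionomycin	Nqo1	non_inflammatory	NA	8.89e-2
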