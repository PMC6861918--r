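gene_id	log2fc	fdr
Nfe2l2	0.094	6.41e-1
Gclm	0.818	1.88e-8
Hmox1	2.860	1.69e-9
Nqo1	0.424	6.45e-3
Nos1	0.038	6.22e-1
Nos2	-0.324	7.05e-7
Nos3	0.203	1.22e-1
Il1a	-0.693	1.08e-4
Il1b	0.478	6.15e-2
Il2	-0.314	6.57e-6
Il4	-0.177	1.38e-4
Il5	-0.149	9.87e-4
Il6	0.409	2.62e-2
Il10	-0.300	3.81e-3
Il12a	-0.409	5.12e-5
Il13	-0.247	1.39e-3
Csf2	-0.211	5.91e-3
Ifng	-0.414	2.19e-2
Tnf	-0.147	5.24e-1
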