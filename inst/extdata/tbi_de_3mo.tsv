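gene_id	log2fc	fdr
Nfe2l2	0.601	6.41e-5
Gclm	0.016	9.51e-1
Hmox1	1.189	2.69e-18
Nqo1	0.646	1.29e-7
Nos1	0.209	3.50e-1
Nos2	0.587	3.32e-2
Nos3	-0.023	9.30e-1
Il1a	-0.089	8.50e-1
Il1b	0.598	NA
Il2	-0.009	NA
Il4	0.095	NA
Il5	NA	NA
Il6	-0.013	NA
Il10	0.161	NA
Il12a	-0.002	9.96e-1
Il13	-0.046	NA
Csf2	NA	NA
Ifng	NA	NA
Tnf	0.088	8.53e-1
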