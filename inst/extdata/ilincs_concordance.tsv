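compound	timepoint	concordance	cell_line	signature_id
desmethylclomipramine	acute	0.123248134	NEU.KCL	LINCSCP_40633
ionomycin	acute	0.11614885	NEU	LINCSCP_41477
trimipramine	acute	0.106234243	NEU	LINCSCP_40955
sirolimus	acute	No score	No score	No score
desmethylclomipramine	chronic	0.239423	NEU.KCL	LINCSCP_40633
ionomycin	chronic	0.225506	NEU.KCL	LINCSCP_40564
trimipramine	chronic	No score	No score	No score
sirolimus	chronic	-0.18388	NPC	LINCSCP_42468
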