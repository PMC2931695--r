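family	member_id	pattern
F$GATA	GATA_1	WGATAR
F$GATA	GATA_2	GATAAG
F$EBOX	EBOX_1	CACGTG
F$TATA	TATA_1	TATAWAW
F$MCB	MCB_1	WCGCGW
F$SCB	SCB_1	CACGAAA
F$STRE	STRE_1	AGGGG
F$STRE	STRE_2	CCCCT
F$PAC	PAC_1	GCGATGAG
F$RRPE	RRPE_1	AAAWTTTT
F$CCAAT	CCAAT_1	CCAAT
F$URS	URS_1	AGCCGCC
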