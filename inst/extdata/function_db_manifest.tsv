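id	label	description
core_PTase	core	UbiA-type prenyltransferase
core_GGPPS	core	geranylgeranyl pyrophosphate synthase
core_FASalpha	core	fatty acid synthase alpha subunit
core_FASbeta	core	fatty acid synthase beta subunit
tail_p450	tailoring	cytochrome P450 monooxygenase
tail_fmo	tailoring	FAD-dependent monooxygenase
tail_omt	tailoring	O-methyltransferase
tail_gt	tailoring	glycosyltransferase
reg_zn2cys6	regulatory	Zn2Cys6 transcription factor
trans_mfs	transport	MFS transporter
trans_abc	transport	ABC transporter
res_pump	resistance	multidrug efflux pump
hk_actin	housekeeping	actin
hk_tubulin	housekeeping	beta-tubulin
hk_gapdh	housekeeping	glyceraldehyde-3-phosphate dehydrogenase
hk_rpl	housekeeping	60S ribosomal protein
hk_hsp70	housekeeping	heat shock protein 70
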