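symbol	panel_id	category	inheritance	evidence	lof_mechanism
TERC	A	telomere	AD	strong	TRUE
TERT	A	telomere	AD_AR	definite	TRUE
TINF2	A	telomere	AD	moderate	FALSE
DKC1	A	telomere	XLR	definite	TRUE
RTEL1	A	telomere	AD_AR	strong	TRUE
PARN	A	telomere	AD	moderate	TRUE
NAF1	A	telomere	AD	strong	TRUE
ZCCHC8	A	telomere	AD	moderate	TRUE
SFTPC	A	non_telomere	AD	strong	FALSE
SFTPA2	A	non_telomere	AD	strong	FALSE
ABCA3	A	non_telomere	AR	strong	TRUE
SFTPA1	A	non_telomere	AD_AR	strong	FALSE
SPDL1	A	non_telomere	AD	limited	FALSE
KIF15	A	non_telomere	AD	limited	FALSE
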