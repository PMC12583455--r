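symbol	panel_id	category	inheritance	evidence	lof_mechanism
MUC5B	B	non_telomere	AD	limited	FALSE
ACTRT3	B	non_telomere	AD	limited	FALSE
AKAP13	B	non_telomere	AD	limited	FALSE
MAD1L1	B	non_telomere	AD	limited	FALSE
RAPGEF2	B	non_telomere	AD	limited	FALSE
SFTPD	B	non_telomere	AD	limited	FALSE
HPS1	B	non_telomere	AR	strong	TRUE
HPS3	B	non_telomere	AR	strong	TRUE
HPS4	B	non_telomere	AR	moderate	TRUE
GLA	B	non_telomere	XLR	definite	TRUE
DPP9	B	non_telomere	AD	moderate	TRUE
FAM111B	B	non_telomere	AD	moderate	FALSE
TSC1	B	non_telomere	AD	definite	TRUE
TSC2	B	non_telomere	AD	definite	TRUE
LIG4	B	non_telomere	AR	strong	TRUE
WRAP53	B	telomere	AR	strong	TRUE
NOP10	B	telomere	AR	moderate	TRUE
NHP2	B	telomere	AR	moderate	TRUE
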