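symbol	panel_id	category	inheritance	evidence	lof_mechanism
POT1	C	telomere	AD	limited	FALSE
TERF1	C	telomere	AD	limited	FALSE
TERF2	C	telomere	AD	limited	FALSE
TERF2IP	C	telomere	AD	limited	FALSE
ACD	C	telomere	AD_AR	moderate	TRUE
CTC1	C	telomere	AR	strong	TRUE
STN1	C	telomere	AR	moderate	TRUE
TEN1	C	telomere	AR	limited	FALSE
RPA1	C	telomere	AD	limited	FALSE
ZNF208	C	telomere	AD	limited	FALSE
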