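term	consequence
stop_gained	nonsense
stopgain	nonsense
nonsense	nonsense
missense_variant	missense
missense	missense
nonsynonymous_SNV	missense
nonsynonymous	missense
frameshift_variant	frameshift
frameshift_insertion	frameshift
frameshift_deletion	frameshift
frameshift	frameshift
splice_acceptor_variant	splice_site
splice_donor_variant	splice_site
splicing	splice_site
splice_site	splice_site
inframe_insertion	inframe_indel
inframe_deletion	inframe_indel
nonframeshift_insertion	inframe_indel
nonframeshift_deletion	inframe_indel
inframe_indel	inframe_indel
synonymous_variant	synonymous
synonymous_SNV	synonymous
synonymous	synonymous
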