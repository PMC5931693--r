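gap_host	recent_transposon	ancestral_element	mb
hg19	hg19_gain	hg19_gain	685.0
hg19	hg19_gain	mm10_loss	37.8
hg19	mm10_loss	hg19_gain	168.0
hg19	mm10_loss	mm10_loss	575.0
hg19	total	total	1465.8
mm10	mm10_gain	mm10_gain	720.6
mm10	mm10_gain	hg19_loss	11.5
mm10	hg19_loss	mm10_gain	356.1
mm10	hg19_loss	hg19_loss	103.4
mm10	total	total	1191.6
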