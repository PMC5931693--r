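metric	hg19	mm10
sequenced_genome_mb	2897.0	2653.0
gaps_outside_nets_mb	111.1	174.0
non_rbh_chains_mb	306.1	293
ancestral_elements_mb	1726.0	1021.0
remaining_chain_blocks_mb	1014.3	994.4
remaining_chain_gaps_mb	1465.8	1191.5
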