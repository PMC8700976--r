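{"name":"GENE1_tx","exon_cds_lengths":[137,356,218,135],"junctions_with_flanks":[1,2,3]}
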