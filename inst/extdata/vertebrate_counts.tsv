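metric	value
n_clades	100
total_sequences	227329
described_species_sampled_clades	29237
species_with_data	11996
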