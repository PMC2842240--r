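group	species_diversity	prop_with_data	resolution_50	resolution_95
Ray-finned fish	29737	0.26	0.14	0.05
Amphibians	6420	0.45	0.30	0.13
Birds	9953	0.63	0.39	0.14
Cartilaginous fish	1158	0.45	0.19	0.04
Crocodilia	23	1.00	0.80	0.60
Mammals	5488	0.62	0.40	0.15
Lamprey	41	0.61	0.32	0.08
Squamates	8396	0.45	0.27	0.09
Turtles	321	0.77	0.59	0.26
All clades	61259	0.41	0.25	0.09
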