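species	family	n_insertions	genome_coverage_pct	divergence_pct
Homo sapiens	MER6	428	0.01	19.2
Pan troglodytes	MER6	411	0.01	19.2
Callithrix jacchus	MER6	364	0.009	21.9
Macaca mulatta	MER6	422	0.01	20.2
Carlito syrichta	MER6	428	0.009	22.9
Microcebus murinus	MER6	385	0.011	19.8
Homo sapiens	MER6A	545	0.01	19.0
Pan troglodytes	MER6A	538	0.01	19.1
Callithrix jacchus	MER6A	482	0.009	21.6
Macaca mulatta	MER6A	544	0.01	19.8
Carlito syrichta	MER6A	648	0.01	22.1
Microcebus murinus	MER6A	544	0.012	19.3
Pteropus vampyrus	MER6A	873	0.023	18.6
Myotis lucifugus	MER6A	544	0.015	19.2
Condylura cristata	MER6A	425	0.012	30.2
Erinaceus europaeus	MER6A	136	0.002	34.9
Solenodon paradoxus	MER6A	871	0.022	27.6
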