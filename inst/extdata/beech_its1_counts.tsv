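item	combined	leaf	root
n_samples	66	33	33
total_reads	370449	248299	122150
quality_reads	228104	149946	78158
motus	4855	2224	2771
nonsingletons	3018	1457	1701
assigned_phylum_only	1725	967	813
assigned_genus_only	525	143	415
assigned_species	462	168	343
unknown	306	179	130
ascomycota	1672	958	799
basidiomycota	935	320	667
zygomycota	97	0	97
other_fungal	8	0	8
ecm	306	0	306
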