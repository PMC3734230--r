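species	total_bp	n_homologs	printed_coverage_pct	mt_genome_length_bp
Arabidopsis thaliana	4803	24	1.3	NA
Brassica napus	8749	23	3.9	NA
Carica papaya	21368	25	4.5	NA
Nicotiana tabacum	11184	37	2.6	NA
Cucurbita pepo	88208	204	9.0	NA
Gossypium hirsutum	6833	27	1.1	621884
Vigna radiata	2109	17	0.5	NA
Vitis vinifera	64357	73	8.3	NA
Ricinus communis	5649	26	1.1	NA
Silene latifolia	1998	16	0.8	NA
Sorghum bicolor	26357	45	5.6	NA
Triticum aestivum	13855	36	3.1	NA
Zea mays	23445	39	4.1	NA
Oryza sativa indica	33176	41	6.7	NA
Oryza sativa japonica	33157	41	6.7	NA
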