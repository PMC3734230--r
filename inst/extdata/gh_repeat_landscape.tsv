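size_class	n_families	total_bp
20-39	192	10747
40-59	69	9667
60-79	35	9567
80-99	11	8365
100-999	32	18368
>=1000	4	117300
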