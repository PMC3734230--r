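(Cycas_taitungensis,(((Triticum_aestivum,(Oryza_rufipogon,(Oryza_sativa_indica,Oryza_sativa_japonica))),(Sorghum_bicolor,(Tripsacum_dactyloides,(Zea_luxurians,(Zea_mays,Zea_perennis))))),(Vitis_vinifera,((((Beta_vulgaris_maritima,Beta_vulgaris_vulgaris),Silene_latifolia),Nicotiana_tabacum),((Vigna_radiata,(Ricinus_communis,(Citrullus_lanatus,Cucurbita_pepo))),(Gossypium_hirsutum,(Carica_papaya,(Arabidopsis_thaliana,(Brassica_juncea,(Brassica_napus,Brassica_oleracea))))))))));
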