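cluster	member	start	end	printed_gap_after
rpl16-rps3	rpl16	593447	593881	-28
rpl16-rps3	rps3	593853	597250	NA
cob-rps14	cob	547956	549134	1363
cob-rps14	rps14	550498	550800	NA
rpl2-rpl5-nad5c	rpl2	532722	533726	497
rpl2-rpl5-nad5c	rpl5	534224	534805	1117
rpl2-rpl5-nad5c	nad5c	535923	535944	NA
nad2abc-sdh3	nad2abc	418598	420365	999
nad2abc-sdh3	sdh3	421265	421699	NA
mttB-nad9	mttB	308702	309502	184
mttB-nad9	nad9	309687	310259	NA
sdh4-cox3	sdh4	258268	258666	-72
sdh4-cox3	cox3	258594	259391	NA
cox1-rps10	cox1	260808	262400	186
cox1-rps10	rps10	262587	263768	NA
atp9-nad5ab	atp9	162829	163140	220
atp9-nad5ab	nad5ab	163361	165659	NA
nad3-rps12	nad3	129383	129754	48
nad3-rps12	rps12	129803	130159	NA
nad1e-matR-nad1d	nad1e	81154	81412	806
nad1e-matR-nad1d	matR	82219	84186	661
nad1e-matR-nad1d	nad1d	84848	84905	NA
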