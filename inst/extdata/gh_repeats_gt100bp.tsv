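no	size_bp	identity_pct	copy1_start	copy1_end	copy2_start	copy2_end	copy3_start	copy3_end	copy4_start	copy4_end	type
R01	27495	99.92	437002	464489	594397	621884	NA	NA	NA	NA	DR
R02	10623	99.81	224949	235564	532802	522190	NA	NA	NA	NA	IR
R03	10302	99.98	130185	140486	340674	330373	NA	NA	NA	NA	IR
R04	10251	99.86	64505	74747	247693	257941	NA	NA	NA	NA	DR
R05	879	100	140497	141375	330372	329494	NA	NA	NA	NA	IR
R06	399	99.5	225720	226118	421200	420802	532032	531634	NA	NA	IR/DR
R07	349	99.43	81010	81358	226466	226118	531286	531634	NA	NA	IR/DR
R08	260	86.54	519189	519438	555385	555140	NA	NA	NA	NA	IR
R09	259	98.07	226519	226775	273990	273734	531233	530978	NA	NA	IR/DR
R10	256	83.2	56397	56644	68151	67904	251342	251095	NA	NA	IR/DR
R11	229	99.13	39574	39802	119894	119666	NA	NA	NA	NA	IR
R12	203	99.51	260466	260668	430908	430706	NA	NA	NA	NA	IR
R13	194	100	70998	71191	254191	254384	427256	427449	NA	NA	DR
R14	175	100	147589	147763	495709	495883	NA	NA	NA	NA	DR
R15	174	98.85	455621	455794	550847	551020	613016	613189	NA	NA	DR
R16	168	91.07	378953	379120	536243	536080	NA	NA	NA	NA	IR
R17	166	94.58	162194	162357	310412	310248	NA	NA	NA	NA	IR
R18	162	91.98	278372	278532	506946	506786	NA	NA	NA	NA	IR
R19	160	97.5	225357	225515	439973	439816	532394	532236	597366	597208	IR/DR
R20	159	99.37	278884	279042	455305	455463	612700	612858	NA	NA	DR
R21	151	100	427472	427622	486639	486489	NA	NA	NA	NA	IR
R22	145	87.59	246993	247137	409294	409158	NA	NA	NA	NA	IR
R23	138	97.1	260510	260645	430864	430729	495627	495763	NA	NA	IR/DR
R24	136	96.32	285066	285201	534095	533960	NA	NA	NA	NA	IR
R25	135	90.37	519189	519320	555385	555255	NA	NA	NA	NA	IR
R26	133	94.74	161921	162053	351301	351169	NA	NA	NA	NA	IR
R27	128	84.38	278561	278686	506757	506635	NA	NA	NA	NA	IR
R28	127	92.91	279043	279168	455473	455598	612868	612993	NA	NA	DR
R29	123	88.62	260519	260638	430855	430736	495636	495755	578212	578092	IR/DR
R30	118	99.15	185254	185371	309736	309619	NA	NA	NA	NA	IR
R31	113	100	81796	81908	438852	438740	596247	596135	NA	NA	IR/DR
R32	113	98.23	86305	86417	307767	307655	NA	NA	NA	NA	IR
R33	107	100	70936	71042	254129	254235	502859	502753	NA	NA	IR/DR
R34	101	85.15	302711	302803	513954	514053	NA	NA	NA	NA	DR
R35	101	97.03	425155	425255	555258	555158	NA	NA	NA	NA	IR
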