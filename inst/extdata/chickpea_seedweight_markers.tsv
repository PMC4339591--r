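marker_id	chromosome_position	motif_unit	motif_count	element	signal	fwd_primer	rev_primer	fragment_min_bp	fragment_max_bp
Ca-CNMS98	CaChr2-3541793	AG	12	GAGA8HVBKN3	(GA)8	TACCACTTTTATACGCTGCAC	ATGAATGAACGAATGTGACTC	145	149
Ca-CNMS99	CaChr2-3544818	GA	10	GAGA8HVBKN3	(GA)8	CCTCTGAAATGGGACTGTT	AACACTTCCCCACACAAAC	137	141
Ca-CNMS100	CaChr2-3547678	GA	13	GAGA8HVBKN3	(GA)8	ATGGAGGCGAATATATAGGAG	TTTTAAGAAACAACTGCGTTC	158	164
Ca-CNMS242	CaChr4-9449939	TTCT	3	CTRMCAMV35S	TCTCTCTCT	ATTTTGATTCTCCTCAGATCC	GAAATCTTTTGCTGCTTATGA	141	145
Ca-CNMS310	CaChr4-41986507	AG	6	CTRMCAMV35S	TCTCTCTCT	TTTTTCTTCTCACTTCGATCA	TAGAAACGAAAGCTGAAAAGC	123	127
Ca-CNMS316	CaChr4-44655063	AG	10	GAGA8HVBKN3	(GA)8	GGACACACAACAGAGAGAAAA	ACGAGGATTGTAAGGAGTACC	163	167
Ca-CNMS352	CaChr5-27283973	ATGGT	3	S1FBOXSORPS1L21	ATGGTA	TCCCATCAAGATGCTAAAATA	AATCAATCTTTGAGTTGTTGC	149	154
Ca-CNMS380	CaChr5-34505910	TC	8	CTRMCAMV35S	TCTCTCTCT	CTTCACCCCTTGGATTTT	GTTGTTGTTGATGCTGTGAC	130	132
Ca-CNMS402	CaChr5-42499426	AG	6	CTRMCAMV35S	TCTCTCTCT	ATGGTTTTGCTCACATTCTTA	AACTCACACAGAACACTGCTT	149	151
Ca-CNMS506	CaChr6-45703332	GA	18	GAGA8HVBKN3	(GA)8	GACATGGTTCGATTTGGAT	CACACTCACTCTCTTCTTCTTCT	153	159
Ca-CNMS539	CaChr7-4624457	AG	8	GAGA8HVBKN3	(GA)8	GAAGTTCTGCCACTGAGTTC	TTAGGAACAGCCTTGTCAAT	153	159
Ca-CNMS544	CaChr7-6052379	CT	11	CTRMCAMV35S	TCTCTCTCT	TCTCTCATCCTCTTTCTTTCC	GATCCAAAGAATGGAATAACC	147	151
Ca-CNMS545	CaChr7-6054880	CAA	7	RAV1AAT	CAACA	CAAGCTCACACTGAACTCTCT	GTTGTTGAGTTGTGGTGATTT	150	156
Ca-CNMS546	CaChr7-6057925	TC	7	CTRMCAMV35S	TCTCTCTCT	TGAGAACAAGACCAGAGTCAC	GTGTTATTGTTGGACCTCAAG	140	144
Ca-CNMS547	CaChr7-6060830	CT	10	CTRMCAMV35S	TCTCTCTCT	ATTCTCCTCATAAGCCATTCT	TTCTCGATCTATACGTCAACC	150	154
Ca-CNMS562	CaChr7-12021223	ACACAA	4	CANBNNAPA	CNAACAC	CCTCTCTTATTTTGTTTGTCAAC	TTCCTTCGAAATTGAGTAAAG	153	165
Ca-CNMS642	CaChr8-3997981	AAG	4	CTRMCAMV35S	TCTCTCTCT	CACCTTCCATCTTCTTCTTCT	TGACAAACTTAATGGGAGAGA	147	155
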