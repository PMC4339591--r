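linkage_group	n_markers	map_length_cM
CaLG1	27	124.3
CaLG2	20	78.9
CaLG3	28	70.6
CaLG4	40	140.3
CaLG5	29	103.4
CaLG6	37	85.4
CaLG7	38	100.5
CaLG8	19	63.5
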