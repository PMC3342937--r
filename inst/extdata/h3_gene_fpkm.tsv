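gene_id	name	group	dividing	nondividing
AT4G40030	HTR4	H3.3	464.6	286.5
AT4G40040	HTR5	H3.3	644.0	351.4
AT5G10980	HTR8	H3.3	154.6	125.7
AT1G09200	HTR2	H3.1	53.4	16.1
AT3G27360	HTR3	H3.1	19.5	3.6
AT5G10390	HTR13	H3.1	16.4	4.4
AT5G10400	HTR9	H3.1	66.5	12.7
AT5G65360	HTR1	H3.1	58.6	22.5
AT1G01370	HTR12	cenH3	3.9	0.7
AT3G44530	HIRA	chaperone	5.7	3.8
AT1G08600	ATRX	chaperone	9.4	6.5
AT1G66740	ASF1A	chaperone	15.9	13.1
AT5G38110	ASF1B	chaperone	14.0	3.9
AT5G58230	MSI1	chaperone	17.3	12.1
AT1G65470	FAS1	chaperone	3.2	2.0
AT5G64630	FAS2	chaperone	5.2	0.7
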