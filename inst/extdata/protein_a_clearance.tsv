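pri	feed	flow_through	flow_through_is_lod	wash	wash_is_lod	eluate	eluate_is_lod
BME	1005	931	FALSE	1	TRUE	1	TRUE
Dextran sulfate	977	691	FALSE	3.3	FALSE	0.5	TRUE
EDTA	1633	1319	FALSE	0.5	TRUE	0.5	TRUE
Polysaccharide	0.47	0.40	FALSE	0.00005	TRUE	0.0001	FALSE
MTG	648	623	FALSE	0.8	TRUE	0.8	TRUE
MSX	81	76	FALSE	0.01	TRUE	0.01	TRUE
PEG8000	16726	15452	FALSE	15	TRUE	15	TRUE
Pluronic F68	33285	29111	FALSE	2.5	TRUE	5	TRUE
Simethicone	240	220	FALSE	1	TRUE	1	TRUE
Triton X-100	10975	9544	FALSE	1.3	FALSE	0.1	TRUE
Tropolone	1938	1681	FALSE	1	TRUE	2.8	FALSE
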