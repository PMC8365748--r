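pri	load	flow_through	flow_through_is_lod	eluate	eluate_is_lod
BME	869	651	FALSE	1	TRUE
Dextran sulfate	643	330	FALSE	45.6	FALSE
EDTA	615	508	FALSE	0.5	TRUE
Polysaccharide	0.47	0.45	FALSE	0.0006	FALSE
MTG	661	520	FALSE	0.8	TRUE
MSX	68	56	FALSE	0.01	TRUE
PEG8000	16797	12539	FALSE	20	TRUE
Simethicone	240	220	FALSE	1.3	TRUE
Triton X-100	9885	5622	FALSE	94.2	FALSE
Tropolone	312	211	FALSE	1.8	TRUE
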