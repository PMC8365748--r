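pri	usage_in_process	molecular_weight	physical_properties	usage_purpose
BME	upstream	78.1	uncharged	support cell growth
Copper ion	upstream	79.5	positively charged	support cell growth and facilitate antibody disulfide bond formation
Caprolactam	upstream; downstream	113.2	uncharged and hydrophobic	leachate from containers and tubes
Dextran sulfate	upstream	4000	negatively charged	prevent cell aggregation
EDTA	downstream	292	negatively charged	prevent enzyme inhibition and disulfide bond reduction
Polysaccharide	upstream	5000	uncharged	support cell growth
MTG	upstream	108.1	uncharged	support cell growth
MSX	cell_banking	180.2	positively charged	support cell selection
PEG8000	upstream; downstream	8000	uncharged	protein stabilizer
Pluronic F68	upstream; downstream	8000	uncharged surfactant	cell shear protectant and protein stabilizer
Simethicone	upstream	238.5	uncharged	antifoam
Triton X-100	downstream	625	nonionic surfactant	virus inactivation
Tropolone	upstream	122.1	hydrophobic	support cell growth
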