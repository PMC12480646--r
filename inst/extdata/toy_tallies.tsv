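sample_id	site_id	event_index	replicate	primer_id	taxon	rank	reads
RiverA_E01_R1	RiverA	1	1	P01	Taxon01	species	1
RiverA_E01_R1	RiverA	1	1	P01	Taxon02	species	2
RiverA_E01_R1	RiverA	1	1	P01	Taxon03	species	3
RiverA_E01_R1	RiverA	1	1	P01	Taxon04	species	14
RiverA_E01_R1	RiverA	1	1	P01	Taxon05	species	80
RiverA_E01_R1	RiverA	1	1	P01	Taxon06	species	300
RiverA_E01_R1	RiverA	1	1	P01	Taxon07	species	9600
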