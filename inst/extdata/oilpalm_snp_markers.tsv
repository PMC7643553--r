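lncrna_id	chrom	pos	context	trait	p_value	nucleotide_types	ave_het
MSTRG.2123	Chr1	26348240	intron	palmitic_acid_C16_0	0.000794231	K G T	0.2301
MSTRG.2168	Chr1	27359487	intron	stearic_acid_C18_0	0.000671054	M C A	0.318
MSTRG.2168	Chr1	27366210	exon	stearic_acid_C18_0	0.000667117	R G A	0.2188
MSTRG.4816	Chr2	10805479	intron	total_oil_content	0.000916663	A G R	0.4067
MSTRG.7396	Chr2	56802941	intron	palmitic_acid_C16_0	0.00038596	G R A	0.1968
MSTRG.7396	Chr2	56803122	intron	palmitic_acid_C16_0	0.000874185	T Y C	0.208
MSTRG.7396	Chr2	56767445	exon	total_oil_content	0.000732102	G R A	0.1425
MSTRG.7397	Chr2	56767445	intron	total_oil_content	0.000732102	A R G	0.2518
MSTRG.10380	Chr3	37185131	intron	linoleic_acid_C18_2	1.49E-09	A G R	0.375
MSTRG.11378	Chr4	4103682	intron	total_oil_content	0.000223078	T W A	0.1605
MSTRG.11378	Chr4	4103761	intron	total_oil_content	0.000414367	T Y C	0.1565
MSTRG.13525	Chr4	50679685	intron	total_oil_content	0.000982483	G A R	0.4258
MSTRG.15295	Chr5	25374494	exon	linoleic_acid_C18_2	0.000862608	A R G	0.4562
MSTRG.15330	Chr5	27273554	intron	total_oil_content	0.000838241	C T Y	0.3712
MSTRG.16341	Chr5	46800615	intron	palmitic_acid_C16_0	0.000916155	Y C T	0.495
MSTRG.16341	Chr5	46773860	intron	linoleic_acid_C18_2	0.000914323	G A R	0.375
MSTRG.16342	Chr5	46773860	intron	linoleic_acid_C18_2	0.000914323	G A R	0.3871
MSTRG.16344	Chr5	46800615	intron	palmitic_acid_C16_0	0.000916155	Y C T	0.495
MSTRG.16345	Chr5	46800615	intron	palmitic_acid_C16_0	0.000916155	G R	0.3432
MSTRG.17117	Chr6	5087561	intron	total_oil_content	0.000433608	T Y C	0.4061
MSTRG.17118	Chr6	5087561	intron	total_oil_content	0.000433608	G R A	0.4283
MSTRG.17644	Chr6	21539684	intron	total_oil_content	0.000343467	C T Y	0.4793
MSTRG.17644	Chr6	21539697	intron	total_oil_content	0.000776114	T C Y	0.4851
MSTRG.28271	Chr11	28838549	intron	total_oil_content	0.000973214	A G R	0.4968
MSTRG.28993	Chr12	15680141	intron	linoleic_acid_C18_2	0.000661354	Y T C	0.475
MSTRG.28993	Chr12	15680161	intron	linoleic_acid_C18_2	0.000820421	R G A	0.4729
MSTRG.29406	Chr12	21510854	intron	stearic_acid_C18_0	0.000778935	G R A	0.1147
MSTRG.30615	Chr13	13106882	intron	total_oil_content	0.000815972	G R	0.1888
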