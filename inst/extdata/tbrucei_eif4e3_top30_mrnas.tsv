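id	description	log2_ratio
Tb927.6.510	GPEET procyclin	5.14
Tb927.11.510	RNA-binding protein, UBP2	4.58
Tb927.6.3490	Zinc finger protein 1	4.31
Tb927.10.1480	Hypothetical protein	4.30
Tb927.6.640	ApaH-like phosphatase ALPH1	4.17
Tb927.1.2310	Hypothetical protein	3.94
Tb927.7.3970	Hypothetical protein	3.56
Tb927.5.2260	Conserved protein	3.50
Tb927.2.3880	Heterogeneous RNP F/H homologue	3.24
Tb927.11.500	RNA-binding protein, UBP1	3.22
Tb927.10.12730	Hypothetical protein	3.02
Tb927.5.820	Hypothetical protein	2.99
Tb927.6.5020	Cyclin 7, putative	2.97
Tb927.8.870	CAMK/CAMKL protein kinase	2.82
Tb927.6.4280	Glyceraldehyde 3-phosphate dehydrogenase, glycosomal	2.77
Tb927.2.2770	Hypothetical protein	2.75
Tb927.11.3760	Hypothetical protein	2.66
Tb927.5.2160	Conserved protein	2.56
Tb927.10.3970	Hypothetical protein	2.51
Tb927.3.2960	Inosine-adenosine-guanosine-nucleosidehydrolase	2.44
Tb927.6.5010	Hypothetical protein	2.40
Tb11.v5.0722	Variant surface glycoprotein (VSG)-related, putative	2.38
Tb927.5.800	Casein kinase I, isoform 2	2.38
Tb927.8.5440	Flagellar calcium-binding 24 kDa protein	2.32
Tb927.11.16820	Hypothetical protein	2.32
Tb927.3.4710	Flagellum attachment zone protein	2.29
Tb927.10.15310	Hypothetical protein	2.28
Tb927.7.2660	Zinc finger protein, ZC3H20	2.28
Tb927.5.1990	Hypothetical protein	2.25
Tb927.11.3310	Ubiquitin-conjugating enzyme	2.24
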