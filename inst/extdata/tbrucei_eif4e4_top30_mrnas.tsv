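id	description	log2_ratio
Tb927.10.13500	60S ribosomal protein L10a	2.66
Tb927.11.11830	40S ribosomal protein S17	2.47
Tb927.11.6300	40S ribosomal protein S5	2.38
Tb927.8.3110	Mitochondrial ribosomal protein S9	2.27
Tb927.8.6890	Succinate dehydrogenase subunit	2.25
Tb927.10.3840	60S ribosomal protein L18a	2.22
Tb927.11.6180	60S ribosomal protein L28	2.15
Tb927.4.3880	Receptor-type adenylate cyclase GRESAG 4	2.14
Tb927.8.4630	Hypothetical protein	2.11
Tb927.9.15380	NADH-ubiquinone oxidoreductase subunit	2.08
Tb927.11.9710	60S ribosomal protein L10a	2.03
Tb927.10.14740	Hypothetical protein	2.02
Tb927.11.740	EIF5A	1.97
Tb927.3.1370	40S ribosomal protein S25	1.87
Tb927.1.710	Phosphoglycerate kinase	1.84
Tb927.10.3850	Hypothetical protein	1.82
Tb927.11.3590	40S ribosomal protein S4	1.82
Tb927.9.8420	QM-like protein	1.79
Tb927.9.7620	60S ribosomal protein L11	1.74
Tb927.11.12040	Cytochrome c oxidase component	1.73
Tb927.1.3180	40S ribosomal protein S11	1.71
Tb927.10.5360	40S ribosomal protein S10	1.69
Tb927.10.3280	60S ribosomal proteins L38	1.68
Tb927.9.8100	Nascent polypeptide associated complex subunit	1.66
Tb927.10.3830	Hypothetical protein	1.66
Tb927.2.6090	60S ribosomal protein L44	1.65
Tb927.9.15420	60S ribosomal protein L32	1.65
Tb927.3.4500	Fumarate hydratase class I	1.64
Tb927.8.3530	Glycerol-3-phosphate dehydrogenase, glycosomal	1.64
Tb927.7.2980	Nitroreductase family	1.61
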