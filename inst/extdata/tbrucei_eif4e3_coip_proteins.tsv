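id	name	description	intensity	ratio	is_bait
Tb927.11.11770	EIF4E3	Eukaryotic translation initiation factor 4E-3	8e8	653.25	TRUE
Tb927.11.10560	EIF4G4	Eukaryotic translation initiation factor 4G type 4	2.1e8	172.19	FALSE
Tb927.7.2340	RPS15	40S ribosomal protein S15	1.6e7	4.14	FALSE
Tb927.7.2140	ZC3H18	Zinc finger protein family member	2.7e7	6.65	FALSE
Tb927.10.1450	CAAP1	Centrin arm-associated protein 1	6.2e7	7.2	FALSE
Tb927.3.3270	PFK	ATP-dependent 6-phosphofructokinase	6.6e7	6.37	FALSE
Tb927.1.880	MDN1	Midasin	4.8e6	15.84	FALSE
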