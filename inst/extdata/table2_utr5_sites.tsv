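species	gene	position	site_offset	fragment
Hsa	CCDC114	261	8	GCAUGCUGGCUCAUGCCUGUAAUCCCAGCACUUUGG
Hsa	DHRS9	1281	8	GCGCGGUGGCUCAUGCCUGUAAUCCCAGCACUUUGG
Hsa	RGS3	205	8	GCGCAGUGGCUCAUGCCUGUAAUCCCAGCACUUUGG
Ptr	RGS3	1	8	GCGCAGUGGCUCAUGCCUGUAAUCCCAGCACUUUGG
Nle	RGS3	205	8	GCACGGUGGCUCAUGCCUGUAAUCCCAGCACUUUGG
Hsa	USP29	2	8	CUGGCCAGGCUCAUGCCUGUAAUCCCAGCACUUUGG
Pab	USP29	52	8	CUGGCCAGGCUCAUGCCUGUAAUCCCAGCACUUUGG
Nle	USP29	52	8	CUGGCCAGGCUCAUGCCUGUAAUCCCAGCACUUUGG
Mle	USP29	47	8	CUGGCCAGGCUCAUGCCUGUAAUCCCAGCACUUUGG
Can	USP29	98	8	CUGGCCAGGCUCAUGCCUGUAAUCCCAGCAUUUUGG
Ggo	USP29	100	8	CUGGCCAGGCUCAUGCCUGUAAUUCCAGCACUUUGG
Rro	USP29	52	8	CUGGCCAGGCUCAUGCCUGUAAUCGCAGCACUUUGG
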