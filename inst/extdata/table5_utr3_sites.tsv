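species	gene	position	site_offset	fragment
Hsa	ADAM17	3466	11	TGGGAGTGGTGGCTCATGCCTGTAATCCCAGCACTTGGAGAGG
Cat	ADAM17	3485	11	GGGGCGCAGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Mmul	ADAM17	3491	11	GGGGCGCGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Mne	ADAM17	3438	11	GGGGCGCGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Ptr	ADAM17	3449	11	TGGGAGTGGTGGCTCATGCCTGTAATCCCAGCACTTGGAGAGG
Rro	ADAM17	3425	11	GGGGCGCGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Hsa	ALDH3A2	2617	11	CGGGCGTGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Cja	ALDH3A2	3444	11	CGGGCGTGGTGGCTCATGCCTGTAATCCCAGCACTTTAGGAGG
Ggo	ALDH3A2	2712	11	CGGGCGTGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Mmul	ALDH3A2	2509	11	CGGACATGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Mne	ALDH3A2	2504	11	CGGACATGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Nle	ALDH3A2	2714	11	TGGTCATGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Pab	ALDH3A2	2297	11	TGGGCATGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Ppa	ALDH3A2	2715	11	CGGGCATGGTGGCTCATGTCTGTAATCCCAGCACTTTGGGAGG
Ptr	ALDH3A2	2711	11	CGGGCATGGTGGCTCATGTCTGTAATCCCAGCACTTTGGGAGG
Rro	ALDH3A2	2727	11	CGGACGTGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGG
Hsa	ARL11	1033	11	TTGGCCCGGTGGCTCATGCCTGTAATCCCAGCACTGTGGGAGA
Cat	ARL11	1642	11	CAGATGCAGTGGCTCATGCCTGTAATCCCAGCACTTTGGGTGG
Mfa	ARL11	1698	11	CAGATGCAGTGGCTCATGCCTGTAATCCCAGCACTTTGGGTGG
Mmul	ARL11	1747	11	CAGATGCAGTGGCTCATGCCTGTAATCCCAGCACTTTGGGTGG
Mne	ARL11	1024	11	TTGGCACGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAGA
Mne	ARL11	1471	11	CAGATGCAGTGGCTCATGCCTGTAATCCCAGCACTTTGGGTGG
Ptr	ARL11	1353	11	CGGGCATGGTGGCTCATGTCTGTAATCCCAGCACTTTGGGAGG
Rro	ARL11	1254	11	CAGGTGCAGTGGCTCATGCCTGTAATCCCAGCACTTTGGGCGG
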