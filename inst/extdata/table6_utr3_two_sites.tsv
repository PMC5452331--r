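species	gene	position	site_offset	fragment
Hsa	ERBB3	4950	11	CGGGCATGGTGGCTCATGCCTGTAATCTCAGCACTTTGGGAG
Hsa	ERBB3	5104	11	TGGGTGCAGTGGCTCATGCCTGTAATCCCAGCCAGCACTTTG
Csa	ERBB3	4989	11	CGGGCATGGTGGCTCATGCCTGTAATCCTAGCACTTTGGGAG
Csa	ERBB3	5149	11	TGGGCGCTGTGGCTCATGCCTGCAATCCCAGCACTTTGGGAG
Mfa	ERBB3	5114	11	TGGGCATGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAG
Mfa	ERBB3	5269	11	TGGGCGCTGTGGCTCATGCCTGCAATCCCAGCCCTTTGGGAG
Mmu	ERBB3	5114	11	TGGGCATGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAG
Mmu	ERBB3	5269	11	TGGGCGCTGTGGCTCATGCCTGCAATCCCAGCCCTTTGGGAG
Mne	ERBB3	5112	11	CGGGCATGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAG
Mne	ERBB3	5267	11	TGGGCGCTGTGGCTCATGCCTGCAATCCCAGCCCTTTGGGAG
Pan	ERBB3	5106	11	CGGGCATGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGAG
Pan	ERBB3	5274	11	TGGGCGCTGTGGCTCATGCCTGCAGTCCCAGCACTTTGGGAG
Ptr	ERBB3	5105	11	CGGGCATGGTGGCTCATGCCTGTAATCTCAGCACTTTGGGAG
Ptr	ERBB3	5243	11	TGGGTGCAGTGGCTCATGCCTGTAATCCCAGCCAGCACTTTG
Mne	FBLIM1	1938	11	TGGGCGTGGTGGCTCATGCCTGTAATCCCTGCACTTTGGGAG
Mne	FBLIM1	5267	11	TGGGCGCTGTGGCTCATGCCTGCAATCCCAGCCCTTTGGGAG
Pab	FKBP14	1514	11	CAGGCACGGTGGCTCACGCCTGTAATCCCAGCACTTCGGGAG
Pab	FKBP14	2128	11	TGGGTGTGGTGGCTCATGCCTGTAATCCCAGCACTTTGGGGG
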