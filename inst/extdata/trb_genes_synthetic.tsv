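species	name	allele	coding_seq	rs5_heptamer	rs5_spacer	rs5_nonamer	rs3_heptamer	rs3_spacer	rs3_nonamer
human	TRBD1	*01	GGGACAGGGGGC	CACTGTG	TGAGTCACTTCA	GGTTTTTGT	CACAGTG	ACAAGGTCTGAGAACCTGGTATA	ACAAAAACC
human	TRBD2	*01	GGGACTAGCGGGGGGG	CACTGTG	CCCAGGTAGAGG	GGTTTCTGT	CACAGTG	TCCTGGAATGCAACTGTGAGCCT	ACAAAAACC
human	TRBD2	*02	GGGACTAGCGGGAGGG	CACTGTG	CCCAGGTAGAGG	GGTTTCTGT	CACAGTG	TCCTGGAATGCAACTGTGAGCCT	ACAAAAACC
human	TRBJ1-1	*01	TGAACACTGAAGCTTTCTTTGGACAAGGCACCAGACTCACAGTTGTAG	CACTGTG	GTTAGTCTGACA	GGTTTTTGT			
human	TRBJ1-2	*01	CTAACTATGGCTACACCTTCGGTTCGGGGACCAGGTTAACCGTTGTAG	CACTGTG	ATTAGTCAGACA	GGTTTTTGT			
human	TRBJ2-1	*01	CTCCTACAATGAGCAGTTCTTCGGGCCAGGGACACGGCTCACCGTGCTAG	CACTGTG	GTCAGTCTTACA	GGTTTTTGT			
human	TRBJ2-2	*01	CAACACCGGGGAGCTGTTTTTTGGAGAAGGCTCTAGGCTGACCGTACTGG	CACTGTG	GTTACTCTGAGA	GGTTTTTGT			
human	TRBJ2-7	*01	CTCCTACGAGCAGTACTTCGGGCCGGGCACCAGGCTCACGGTCACAGGG	CACTGTG	GTTAGACTGAGA	GGTTTTTGT			
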