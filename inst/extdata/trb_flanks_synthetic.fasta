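>flank5 synthetic genomic context upstream of the TRBD1 5' recombination signal
TCCTAGGATCAGGTTCATGGTTCTCAAGTCATCCTGCAAAGCTGGAGTCACAGAAGTCAT
>flank3 synthetic genomic context downstream of the TRBD2 3' recombination signal
GTCGACTTGGTCAACCTGGTGAGTCCTTTAGACCTCATGACCAGGAAGTCGCTTCTCACT
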