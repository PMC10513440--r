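Species	Dir primer sequence	Length	Rev primer sequence	Length
Human	5’-ACCCAGGAGGAAAGAAGAGGACT-3’	23	5’-GTGATGCATGTTCCAAGGAGGG-3’	22
Rat	5’-TTGTAAAGGTTTCCCATAGAATTG-3’	24	5’-AGGGGAAACCCAGTGACATAG-3’	21
Mouse	5’-GTAAAGGCTTCCCATAGAAT-3’	20	5’-TGATATAGATGTTCTCCCAG-3’	20
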