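>TP53_intron6_synthetic 120 nt; GT donor, AG acceptor, cryptic AG acceptor 49 nt upstream of the exon 7 junction
GTCCTAGGTTTTTACGTGTCGAGGACTCCACTCACTAGTGCGAAAGTGCGGCTCATTCCA
TCCCGTTCAAGTCTTTCGCTTCTCTCTGCCTCGCTGTCCTCCGCTCTGGCTCGGGCCCAG
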