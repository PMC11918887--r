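# The ten introns of TP53 (11-exon gene structure). Anchors are the HGVS cDNA
# positions adjacent to each splice site: donor_anchor is the last base of the
# upstream exon, acceptor_anchor the first base of the downstream exon.
# Intron 1 lies entirely in the 5' UTR; its anchors use HGVS 5' UTR
# coordinates (the exon 1 / exon 2 junction sits 28 nt upstream of the start
# codon, i.e. exon 2 begins at c.-28).
# sequence_file: FASTA with the intron sequence, where available. Only the
# intron 6 sequence ships with the package; it is a SYNTHETIC stand-in (see
# tp53_intron6_synthetic.fa) constructed to carry the documented cryptic
# acceptor 49 nt upstream of the canonical exon 7 junction. All other introns
# are sequence-absent and splice-consequence prediction degrades gracefully.
intron	donor_anchor	acceptor_anchor	sequence_file
1	-29	-28	NA
2	74	75	NA
3	96	97	NA
4	375	376	NA
5	559	560	NA
6	672	673	tp53_intron6_synthetic.fa
7	782	783	NA
8	919	920	NA
9	993	994	NA
10	1100	1101	NA
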