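# SYNTHETIC 11-SNP panel for the TP53 locus, used as the default panel for
# copy-neutral LOH inference and for simulated SNP profiles. Identifiers and
# locus offsets are invented; any user panel with the same columns may be
# supplied instead.
snp_id	position
SNP01	1150
SNP02	2840
SNP03	4410
SNP04	5660
SNP05	7025
SNP06	8190
SNP07	9470
SNP08	10840
SNP09	12300
SNP10	13720
SNP11	15080
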