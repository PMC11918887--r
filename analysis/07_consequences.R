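#!/usr/bin/env Rscript
# Protein-level consequences of the CLL-specific truncating hotspots: the
# codon 209 frameshift (p.Arg209LysfsTer6, 5 novel residues), the recurrent
# nonsense variants p.Arg196Ter and p.Arg213Ter, and the intron 6 acceptor
# variants that re-route splicing to the cryptic acceptor 49 nt upstream
# (p53psi-type isoform: frame shifts through the retained intron and stops
# at the start of exon 7).

suppressMessages(library(tp53cll))
model <- tp53_model()

tab <- consequence_table(
  c("c.626_627del", "c.586C>T", "c.637C>T",
    "c.673-2A>G", "c.673-2A>T", "c.673-2A>C", "c.700T>C"),
  model,
  file = "results/consequences.tsv",
  fasta = "results/predicted_products.fa")
print(tab)

out <- predict_splice_outcome("c.673-2A>G", model)
cat("\nc.673-2A>G splice outcome:\n")
print(out)
cat("retained intronic sequence (", nchar(out$retained_sequence),
    " nt):\n", out$retained_sequence, "\n", sep = "")
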