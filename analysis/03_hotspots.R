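#!/usr/bin/env Rscript
# Hotspot analyses: the frameshift hotspot c.626_627del (p.Arg209LysfsTer6)
# as a share of frameshifts, the intron 6 acceptor variants (c.673-2) as a
# share of splice variants, chi-square enrichment of the frameshift hotspot
# against a pan-cancer comparator share (~2%), and the inverted-repeat
# hairpin context around codons 209-210 that plausibly drives the deletion.

suppressMessages(library(tp53cll))
co <- load_cohort("results/cohort.tsv")
model <- tp53_model()

fd <- frameshift_codon_distribution(co)
write.table(fd, "results/frameshift_codons.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
share_626 <- sum(fd$proportion[fd$hgvs_c == "c.626_627del"])
cat("c.626_627del:", round(100 * share_626, 1), "% of", sum(fd$n),
    "frameshift variants (modal frameshift:", fd$hgvs_c[1], ")\n")

enr <- hotspot_enrichment(round(share_626 * sum(fd$n)), sum(fd$n),
                          20L, 1000L)
cat("enrichment vs a 2% comparator share: chi2 =",
    round(enr$statistic, 1), ", p =", format(enr$p_value, digits = 3),
    ", OR =", round(enr$odds_ratio, 1), "\n")

sp <- splice_signal_distribution(co, model)
write.table(sp$by_signal, "results/splice_signals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sp$by_position, "results/splice_positions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
share_673 <- sum(sp$by_position$proportion[sp$by_position$position ==
                                             "673-2"])
cat("intron 6 acceptor (c.673-2):", round(100 * share_673, 1), "% of",
    sum(sp$by_signal$n), "splice variants\n")

ir <- inverted_repeat_context(model, c(625L, 630L), arm_len = 4L,
                              max_spacer = 4L)
cat("inverted repeats flanking c.625-630 (arm 4, spacer <= 4):\n")
print(ir)
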