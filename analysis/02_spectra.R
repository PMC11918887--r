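#!/usr/bin/env Rscript
# Load and annotate the cohort, then compute the variant-class spectrum and
# the six-class mutational-event spectrum.  The class spectrum should sit
# near 73/11/2/6/8 percent (missense/frameshift/inframe/nonsense/splice)
# and the events should show the CLL-typical AT>GC excess (~20%) next to
# the CpG-driven GC>AT transitions.

suppressMessages(library(tp53cll))
co <- load_cohort("results/cohort.tsv")
print(co)

cs <- class_spectrum(co)
write.table(cs, "results/class_spectrum.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nvariant-class spectrum (% of variants):\n")
print(transform(cs, pct = round(100 * proportion, 1)))

es <- event_spectrum(co)
write.table(es, "results/event_spectrum.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nmutational events (% of substitutions; n_cpg = CpG-context GC>AT):\n")
print(transform(es, pct = round(100 * proportion, 1)))
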