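#!/usr/bin/env Rscript
# Subclonal architecture at the table level: per-patient multiclonality
# (SM/DM/MM3/MM4plus), cumulated VAF (never above 100% -- variants sit on
# different alleles or in independent subclones), the 1-5% low-VAF census
# that Sanger sequencing would miss, and VAF comparisons across
# pathogenicity classes (expected null).

suppressMessages(library(tp53cll))
co <- load_cohort("results/cohort.tsv")

mc <- multiclonality(co)
write.table(mc$per_patient, "results/multiclonality_per_patient.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("NGS multiclonality histogram (", mc$n_multi, "of", mc$n_patients,
    "patients multi-mutated, range",
    paste(mc$range, collapse = "-"), "):\n")
print(mc$histogram)

cv <- cumulated_vaf(co)
write.table(cv, "results/cumulated_vaf.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nmax cumulated VAF:", max(cv$cum_vaf), "%;",
    sum(cv$exceeds_100), "patients exceed 100%\n")

cen <- low_vaf_census(co)
cat("\n1-5% VAF band:", cen$n_variants, "variants;", cen$n_patients,
    "patients (", cen$n_patients_single, "single-mutated /",
    cen$n_patients_multi, "multi-mutated )\n")

vg <- vaf_group_comparison(co)
write.table(vg, "results/vaf_by_pathogenicity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nVAF by pathogenicity label (rank-sum, expect no separation):\n")
print(vg)
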