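# Shared fixtures: toy gene models and small cohort tables, built in code.

TP53 <- tp53_model()

# Two-exon toy gene, 30-nt CDS, one intron with a single marked cryptic AG.
#   exon1 = codons 1..5, exon2 = codons 6..10
toy_model <- function() {
  cds <- paste0("ATGGCTGAAACCTGG",   # M A E T W
                "TTCGGTCATAAATAA")   # F G H K *
  #   intron: donor GT ... cryptic AG at offset 8 (8-nt retention) ... AG
  intron <- "GTCCTTCCCTTAGTCCTCCAG"
  gene_model(cds,
             data.frame(exon = 1:2, cdna_start = c(1L, 16L),
                        cdna_end = c(15L, 30L)),
             transcript_id = "TOY", protein_id = "TOYP",
             introns = data.frame(intron = 1L, donor_anchor = 15L,
                                  acceptor_anchor = 16L, seq = intron))
}

# Minimal cohort table rows in the input schema.
cohort_row <- function(patient_id, hgvs_c, assay = "NGS", vaf = 20,
                       pathogenicity = "P", del17p = NA,
                       treatment = NA) {
  data.frame(patient_id = patient_id, assay = assay, hgvs_c = hgvs_c,
             vaf = if (assay == "NGS") vaf else NA_real_,
             pathogenicity = pathogenicity, del17p = del17p,
             treatment = treatment, stringsAsFactors = FALSE)
}
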