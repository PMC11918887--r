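Package: tp53cll
Title: TP53 Mutation Spectrum, Multiclonality and Allele Architecture in
    Chronic Lymphocytic Leukemia
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for TP53-mutated chronic lymphocytic leukemia
    (CLL) cohorts reported in HGVS cDNA nomenclature on transcript NM_000546.
    Parses and normalizes coding variant descriptions, classifies variants
    and their mutational events (six-class substitution spectrum, CpG
    context), and computes cohort-level statistics: variant-class spectra,
    per-patient multiclonality, cumulated variant allele frequency, low-VAF
    census, and hotspot enrichment between cohorts.  Predicts protein-level
    consequences including frameshift translation with HGVS p. naming,
    nonsense truncation, and disruption of the intron 6 splice acceptor with
    cryptic-acceptor (p53psi-type) isoform construction.  Determines cis or
    trans configuration of co-occurring variants from sequencing reads,
    reconstructs allele tables from long reads, and infers copy-neutral loss
    of heterozygosity from SNP allele fractions.  A seeded simulator
    generates cohorts, reads and SNP profiles with the clonal structure the
    analyses assume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
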