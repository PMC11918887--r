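# Copy-neutral LOH inference from per-SNP allele fractions at the TP53
# locus, combined with the variant VAF and the FISH del(17p) status.

#' Genotype locus SNPs from allele fractions
#'
#' A SNP is heterozygous when its alternate-allele fraction falls inside the
#' het band at sufficient depth, homozygous (ref or alt) outside the band,
#' and uninformative below the depth cutoff.
#'
#' @param profile Data frame with columns `snp_id`, `position`,
#'   `alt_fraction` (0..1), `depth`.
#' @param het_band Numeric length-2: the heterozygous band on the alternate
#'   fraction (default `c(0.10, 0.90)`).
#' @param min_depth Minimum read depth for an informative genotype
#'   (default 100).
#' @return The profile with an added `genotype` column
#'   (het/hom_ref/hom_alt/uninformative).
#' @export
genotype_snps <- function(profile, het_band = c(0.10, 0.90),
                          min_depth = 100L) {
  profile <- as.data.frame(profile)
  need <- c("snp_id", "position", "alt_fraction", "depth")
  if (!all(need %in% names(profile)))
    stop("SNP profile needs columns: ", paste(need, collapse = ", "))
  if (nrow(profile) == 0L) stop("empty SNP profile")
  if (any(profile$alt_fraction < 0 | profile$alt_fraction > 1))
    stop("alt_fraction must lie in [0,1]")
  if (any(profile$depth <= 0)) stop("depth must be positive")
  gt <- ifelse(profile$depth < min_depth, "uninformative",
        ifelse(profile$alt_fraction >= het_band[1L] &
                 profile$alt_fraction <= het_band[2L], "het",
        ifelse(profile$alt_fraction < het_band[1L], "hom_ref", "hom_alt")))
  profile$genotype <- gt
  profile
}

#' Infer copy-neutral LOH at the TP53 locus
#'
#' Decision rule for the dominant clone: `cn_loh` requires a variant VAF
#' above 50%, no del(17p), and homozygosity of every informative SNP
#' (consistent with replacement of the wild-type locus by the mutant
#' allele); `hemizygous` when del(17p) is present (a VAF above 50% then
#' reflects the single remaining allele, not copy-neutral LOH);
#' `heterozygous` when at least one informative SNP is heterozygous;
#' `uninformative` when no SNP passes the depth cutoff.  CN-LOH restricted
#' to minor subclones is deliberately not called.
#'
#' @param genotypes Output of [genotype_snps()] (or a raw profile, genotyped
#'   with defaults).
#' @param variant_vaf The patient's TP53 variant VAF in percent.
#' @param del17p `"no"`, `"yes"` or `"unknown"` (FISH status; consumed, not
#'   derived).
#' @return A `cnloh_call`: `call`, `n_informative_snps`, `n_het_snps`,
#'   `evidence` (per-SNP genotypes), `variant_vaf`, `del17p`.
#' @export
infer_cnloh <- function(genotypes, variant_vaf,
                        del17p = c("no", "yes", "unknown")) {
  del17p <- match.arg(del17p)
  if (is.null(genotypes$genotype)) genotypes <- genotype_snps(genotypes)
  inf <- genotypes[genotypes$genotype != "uninformative", ]
  n_het <- sum(inf$genotype == "het")
  call <- if (nrow(inf) == 0L) "uninformative"
    else if (del17p == "yes") "hemizygous"
    else if (n_het >= 1L) "heterozygous"
    else if (variant_vaf > 50 && del17p == "no") "cn_loh"
    else "uninformative"
  reason <- if (nrow(inf) == 0L) "no SNP passed the depth cutoff"
    else if (call == "uninformative")
      "all informative SNPs homozygous but VAF does not exceed 50%"
    else NA_character_
  structure(list(call = call, n_informative_snps = nrow(inf),
                 n_het_snps = n_het, evidence = genotypes,
                 variant_vaf = variant_vaf, del17p = del17p,
                 reason = reason),
            class = "cnloh_call")
}

#' @export
print.cnloh_call <- function(x, ...) {
  cat("<cnloh_call> ", x$call, " (VAF ", x$variant_vaf, "%, del17p ",
      x$del17p, "; ", x$n_het_snps, "/", x$n_informative_snps,
      " informative SNPs het)\n", sep = "")
  if (!is.na(x$reason)) cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}

#' The packaged synthetic 11-SNP panel
#'
#' Identifiers and locus offsets are synthetic; any panel data frame with
#' columns `snp_id`, `position` may be used instead.
#'
#' @return Data frame with `snp_id`, `position`.
#' @export
default_snp_panel <- function() {
  utils::read.delim(system.file("extdata", "snp_panel_synthetic.tsv",
                                package = "tp53cll", mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
}
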