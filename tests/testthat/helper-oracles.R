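# Independent oracles used across the suite.  They share no code with the
# package paths they check: translation is a codon-table loop, mutation is
# direct string surgery, the chi-square is the closed form, and the
# inverted-repeat scan is an exhaustive window enumeration.

GC <- Biostrings::GENETIC_CODE

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(unname(GC[codons]), collapse = "")
}

# Apply a variant, described by its parsed fields, to a sequence by plain
# string surgery.
oracle_apply <- function(seq, kind, s, e, ref = "", alt = "") {
  before <- substring(seq, 1L, s - 1L)
  switch(kind,
    substitution = paste0(before, alt, substring(seq, s + 1L)),
    deletion = paste0(before, substring(seq, e + 1L)),
    insertion = paste0(substring(seq, 1L, s), alt, substring(seq, s + 1L)),
    duplication = paste0(substring(seq, 1L, e), substring(seq, s, e),
                         substring(seq, e + 1L)),
    delins = paste0(before, alt, substring(seq, e + 1L)))
}

# Full mutate-translate-diff: returns the variant class plus, for
# truncating changes, the first changed residue and the stop position.
oracle_consequence <- function(cds, kind, s, e, ref = "", alt = "") {
  refp_full <- oracle_translate(cds)
  stopr <- regexpr("*", refp_full, fixed = TRUE)
  refp <- substring(refp_full, 1L, stopr - 1L)
  mut <- oracle_apply(cds, kind, s, e, ref, alt)
  mutp_full <- oracle_translate(mut)
  stopm <- regexpr("*", mutp_full, fixed = TRUE)
  mutp <- if (stopm > 0L) substring(mutp_full, 1L, stopm - 1L) else mutp_full
  if (kind == "substitution") {
    cls <- if (mutp_full == refp_full) "synonymous"
      else if (nchar(mutp) < nchar(refp) && stopm > 0L &&
                 substring(refp, 1L, nchar(mutp)) == mutp) "nonsense"
      else "missense"
  } else {
    net <- switch(kind, deletion = -(e - s + 1L), insertion = nchar(alt),
                  duplication = e - s + 1L,
                  delins = nchar(alt) - (e - s + 1L))
    cls <- if (net %% 3L != 0L) "frameshift" else "inframe_indel"
  }
  i <- 1L
  while (i <= min(nchar(refp), nchar(mutp)) &&
         substring(refp, i, i) == substring(mutp, i, i)) i <- i + 1L
  list(class = cls, mut_protein = mutp,
       first_diff = i, has_stop = stopm > 0L,
       fs_ter = if (stopm > 0L) nchar(mutp) - i + 2L else NA_integer_)
}

chi2_oracle <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp)^2 / exp)
}

# Exhaustive inverted-repeat enumeration over a sequence.
ir_oracle <- function(seq, range, arm_len, max_spacer) {
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  L <- nchar(seq)
  hits <- list()
  for (i in seq_len(max(0L, L - 2L * arm_len)))
    for (sp in 0:max_spacer) {
      j <- i + arm_len + sp
      if (j + arm_len - 1L > L) next
      if (substring(seq, i, i + arm_len - 1L) ==
            rc(substring(seq, j, j + arm_len - 1L)) &&
          i <= range[2L] && j + arm_len - 1L >= range[1L])
        hits[[length(hits) + 1L]] <- c(i, j, sp)
    }
  hits
}

# Random CDS: uniform non-stop codons, terminated by a stop.
random_cds <- function(n_codons) {
  codons <- names(GC)[GC != "*"]
  codons <- codons[substring(codons, 1, 1) %in% c("A", "C", "G", "T")]
  paste0("ATG", paste(sample(codons, n_codons - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}
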