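# Read-backed cis/trans phasing of co-occurring variants, and whole-amplicon
# allele reconstruction from long reads.
#
# Reads are consumed either from a simplified long-format call table
# (read_id, variant, call in ref|alt|uncalled) or from SAM, in which case
# per-read allele calls at substitution positions are extracted from the
# alignment (unmapped, secondary and duplicate reads skipped; soft-clipped
# or deleted positions uncalled).

#' Are two variants eligible for short-read phasing?
#'
#' Short reads can phase a pair only when both variants are exonic, lie in
#' the same exon, and are close enough for one read to span both.
#'
#' @param v1,v2 `coding_variant`s or HGVS strings.
#' @param model A `gene_model`.
#' @param max_dist Maximum cDNA distance in nucleotides (default 50,
#'   inclusive).
#' @return TRUE or FALSE.
#' @export
pair_eligibility <- function(v1, v2, model, max_dist = 50L) {
  if (is.character(v1)) v1 <- parse_hgvs_c(v1)
  if (is.character(v2)) v2 <- parse_hgvs_c(v2)
  if (!is_exonic(v1) || !is_exonic(v2)) return(FALSE)
  e1 <- exon_of(model, v1$start); e2 <- exon_of(model, v2$start)
  if (is.na(e1) || is.na(e2) || e1 != e2) return(FALSE)
  abs(v1$start - v2$start) <= max_dist
}

# Normalize a calls object into the long data frame form.
as_calls <- function(calls) {
  calls <- as.data.frame(calls)
  need <- c("read_id", "variant", "call")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  calls$call <- tolower(calls$call)
  bad <- !calls$call %in% c("ref", "alt", "uncalled")
  if (any(bad)) stop("calls must be ref/alt/uncalled")
  calls
}

#' Read a simplified per-read call table
#'
#' @param path TSV with columns `read_id`, `variant`, `call`
#'   (ref/alt/uncalled).
#' @return Long-format calls data frame.
#' @export
read_calls_tsv <- function(path) {
  as_calls(utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE))
}

#' Phase a variant pair from doubly-called reads
#'
#' Counts the four haplotype classes over reads that confidently call both
#' positions, then decides the configuration: a haplotype class is *present*
#' when its count reaches `min_support` and exceeds the error-consistent
#' bound, *absent* when its count is at or below that bound (the
#' `conf`-quantile of Binomial(n, error_rate)).  The pair is `cis` when the
#' double-alt haplotype is present and both single-alt haplotypes are
#' absent, `trans` when both single-alt haplotypes are present and the
#' double-alt haplotype is absent, and `ambiguous` otherwise -- so cis and
#' trans are disjoint by construction.
#'
#' @param calls Long-format calls (read_id, variant, call) or a path/SAM via
#'   [read_calls_tsv()] / [sam_allele_calls()].
#' @param v1,v2 Variant identifiers as used in the calls table.
#' @param min_support Minimum reads supporting a haplotype (default 20).
#' @param error_rate Per-site miscall rate (default 0.005).
#' @param conf Quantile for the error-consistent bound (default 0.999).
#' @return A `phase_call`: counts `n_ref_ref`, `n_alt_ref`, `n_ref_alt`,
#'   `n_alt_alt`, `configuration` (cis/trans/ambiguous), thresholds, and a
#'   `reason` when ambiguous.
#' @export
phase_pair <- function(calls, v1, v2, min_support = 20L, error_rate = 0.005,
                       conf = 0.999) {
  calls <- as_calls(calls)
  c1 <- calls[calls$variant == v1, c("read_id", "call")]
  c2 <- calls[calls$variant == v2, c("read_id", "call")]
  m <- merge(c1, c2, by = "read_id", suffixes = c("_1", "_2"))
  m <- m[m$call_1 != "uncalled" & m$call_2 != "uncalled", ]
  n <- c(n_ref_ref = sum(m$call_1 == "ref" & m$call_2 == "ref"),
         n_alt_ref = sum(m$call_1 == "alt" & m$call_2 == "ref"),
         n_ref_alt = sum(m$call_1 == "ref" & m$call_2 == "alt"),
         n_alt_alt = sum(m$call_1 == "alt" & m$call_2 == "alt"))
  nd <- sum(n)
  out <- structure(list(pair = c(v1, v2), counts = n,
                        n_double_called = nd,
                        configuration = "ambiguous",
                        min_support = min_support, error_rate = error_rate,
                        error_bound = NA_real_, reason = NA_character_),
                   class = "phase_call")
  if (nd < min_support) {
    out$reason <- paste0("insufficient coverage: ", nd,
                         " doubly-called reads < ", min_support)
    return(out)
  }
  bound <- stats::qbinom(conf, nd, error_rate)
  out$error_bound <- bound
  present <- function(k) k >= min_support && k > bound
  absent <- function(k) k <= bound
  if (present(n[["n_alt_alt"]]) && absent(n[["n_alt_ref"]]) &&
      absent(n[["n_ref_alt"]]))
    out$configuration <- "cis"
  else if (present(n[["n_alt_ref"]]) && present(n[["n_ref_alt"]]) &&
           absent(n[["n_alt_alt"]]))
    out$configuration <- "trans"
  else
    out$reason <- "haplotype counts fit neither configuration cleanly"
  out
}

#' @export
print.phase_call <- function(x, ...) {
  cat("<phase_call> ", paste(x$pair, collapse = " / "), ": ",
      x$configuration, "\n  counts: ", paste(names(x$counts), x$counts,
                                             sep = "=", collapse = ", "),
      "\n", sep = "")
  if (!is.na(x$reason)) cat("  reason: ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Reconstruct the allele table from spanning long reads
#'
#' Groups reads that call every variant position by their full
#' variant-combination signature and reports counts and frequencies,
#' including the wild-type allele.  Signatures below a noise floor are
#' flagged as possible chimeras or sequencing errors.
#'
#' @param calls Long-format calls data frame.
#' @param variants Character vector of variant identifiers to reconstruct
#'   over.
#' @param noise_floor Frequency below which a signature is flagged
#'   (default 0.01).
#' @return An `allele_table` data frame: `signature` (`"wt"` or `+`-joined
#'   variant names), `n`, `frequency`, `flagged`; dropped non-spanning reads
#'   in `attr(, "n_dropped")`.
#' @export
reconstruct_alleles <- function(calls, variants, noise_floor = 0.01) {
  calls <- as_calls(calls)
  calls <- calls[calls$variant %in% variants, ]
  wide <- split(calls, calls$read_id)
  sigs <- vapply(wide, function(d) {
    if (!all(variants %in% d$variant)) return(NA_character_)
    cc <- d$call[match(variants, d$variant)]
    if (any(cc == "uncalled")) return(NA_character_)
    alt <- variants[cc == "alt"]
    if (length(alt) == 0L) "wt" else paste(alt, collapse = "+")
  }, character(1L))
  n_dropped <- sum(is.na(sigs))
  sigs <- sigs[!is.na(sigs)]
  if (length(sigs) == 0L) stop("no reads span all variant positions")
  tab <- sort(table(sigs), decreasing = TRUE)
  out <- data.frame(signature = names(tab), n = as.integer(tab),
                    frequency = as.integer(tab) / length(sigs))
  out$flagged <- out$frequency < noise_floor
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("allele_table", "data.frame")
  out
}

# --- SAM support -----------------------------------------------------------

# Base of `seq` aligned over reference position `target`, or NA when the
# position is soft-clipped, deleted or not covered.
base_at <- function(pos, cigar, seq, target) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  rpos <- pos                            # next reference position
  qpos <- 1L                             # next query position
  for (op in ops) {
    len <- as.integer(substr(op, 1L, nchar(op) - 1L))
    type <- substr(op, nchar(op), nchar(op))
    if (type %in% c("M", "=", "X")) {
      if (target >= rpos && target < rpos + len)
        return(substr(seq, qpos + (target - rpos), qpos + (target - rpos)))
      rpos <- rpos + len; qpos <- qpos + len
    } else if (type %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (type %in% c("D", "N")) {
      if (target >= rpos && target < rpos + len) return(NA_character_)
      rpos <- rpos + len
    }                                    # H, P consume nothing
  }
  NA_character_
}

#' Extract per-read allele calls at substitution positions from SAM
#'
#' Converts the SAM to BAM via Rsamtools, walks each primary alignment's
#' CIGAR, and calls ref/alt/uncalled at every queried position.  A base
#' matching neither the reference nor the alternate allele is conservatively
#' uncalled.
#'
#' @param sam_path Path to a SAM file with a valid header.
#' @param variants Data frame with columns `variant` (identifier), `pos`
#'   (1-based reference position), `ref`, `alt` (single bases).
#' @return Long-format calls data frame usable by [phase_pair()] and
#'   [reconstruct_alleles()].
#' @export
sam_allele_calls <- function(sam_path, variants) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("variant", "pos", "ref", "alt") %in% names(variants)))
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flags,
                                 what = c("qname", "pos", "cigar", "seq"))
  aln <- Rsamtools::scanBam(bam, param = par)[[1L]]
  seqs <- as.character(aln$seq)
  out <- vector("list", length(aln$qname) * nrow(variants))
  k <- 0L
  for (i in seq_along(aln$qname)) {
    for (j in seq_len(nrow(variants))) {
      b <- base_at(aln$pos[i], aln$cigar[i], seqs[i], variants$pos[j])
      call <- if (is.na(b)) "uncalled"
              else if (b == variants$ref[j]) "ref"
              else if (b == variants$alt[j]) "alt"
              else "uncalled"
      k <- k + 1L
      out[[k]] <- data.frame(read_id = aln$qname[i],
                             variant = variants$variant[j], call = call,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}
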