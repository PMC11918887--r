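# HGVS c. parsing, formatting, normalization and classification.
#
# Supported grammar (a deliberate subset of HGVS on one coding transcript):
#   substitution  c.700T>C, c.673-2A>G, c.-29+1G>A
#   deletion      c.626_627del, c.626_627delAG, c.629del
#   duplication   c.529dup, c.529_534dup
#   insertion     c.100_101insTT
#   deletion-insertion  c.97_98delinsTG
# Positions are 1-based HGVS cDNA coordinates; intronic positions are written
# anchor+offset / anchor-offset; 5' UTR anchors are negative.  Inversions,
# conversions, protein-level input and multi-transcript forms are rejected
# with an explicit "unsupported" error.

POS_RE <- "(-?\\d+)([+-]\\d+)?"

new_coding_variant <- function(kind, start, start_offset, end, end_offset,
                               ref = "", alt = "", raw = NA_character_) {
  v <- structure(list(raw = raw, kind = kind,
                      start = as.integer(start),
                      start_offset = as.integer(start_offset),
                      end = as.integer(end),
                      end_offset = as.integer(end_offset),
                      ref = ref, alt = alt),
                 class = "coding_variant")
  if (v$start == 0L || v$end == 0L)
    stop("HGVS cDNA coordinates have no position 0")
  if (v$start > v$end || (v$start == v$end && v$start_offset > v$end_offset))
    stop("variant range start must not lie 3' of its end: ",
         if (is.na(raw)) "" else raw)
  v
}

#' Parse an HGVS c. variant description
#'
#' Accepts descriptions with or without a transcript prefix (`NM_000546_`,
#' `NM_000546:`) and with or without the leading `c.`.
#'
#' @param text A single HGVS c. description.
#' @return A `coding_variant` object with fields `kind` (substitution,
#'   deletion, duplication, insertion, delins), `start`/`start_offset`,
#'   `end`/`end_offset`, `ref`, `alt`.
#' @export
parse_hgvs_c <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("expected a single non-empty HGVS string")
  raw <- text
  s <- gsub("\\s", "", text)
  s <- sub("^[A-Z]{2}_\\d+(\\.\\d+)?[_:]", "", s)
  s <- sub("^c\\.", "", s)
  if (grepl("inv|con|\\[|\\(|;|=", s) || grepl("^p\\.", s))
    stop("unsupported HGVS feature in '", raw,
         "': only substitutions, del, dup, ins and delins on the coding ",
         "transcript are handled")
  m <- regmatches(s, regexec(paste0("^", POS_RE, "([ACGT])>([ACGT])$"), s))[[1L]]
  if (length(m)) {
    off <- if (nzchar(m[3L])) as.integer(m[3L]) else 0L
    return(new_coding_variant("substitution", m[2L], off, m[2L], off,
                              ref = m[4L], alt = m[5L], raw = raw))
  }
  range_re <- paste0("^", POS_RE, "(?:_", POS_RE, ")?")
  for (kind in c("delins", "del", "dup", "ins")) {
    pat <- paste0(range_re, kind,
                  if (kind %in% c("ins", "delins")) "([ACGT]+)$" else "([ACGT]*)$")
    m <- regmatches(s, regexec(pat, s))[[1L]]
    if (!length(m)) next
    s1 <- as.integer(m[2L])
    o1 <- if (nzchar(m[3L])) as.integer(m[3L]) else 0L
    s2 <- if (nzchar(m[4L])) as.integer(m[4L]) else s1
    o2 <- if (nzchar(m[5L])) as.integer(m[5L]) else if (nzchar(m[4L])) 0L else o1
    seq <- m[6L]
    if (kind == "ins") {
      if (!nzchar(m[4L]))
        stop("insertion needs a two-position range flanking the insertion ",
             "point: ", raw)
      if (o1 != 0L || o2 != 0L)
        stop("unsupported HGVS feature in '", raw,
             "': intronic insertions are not handled")
      if (s2 != s1 + 1L)
        stop("insertion positions must be adjacent: ", raw)
      return(new_coding_variant("insertion", s1, 0L, s2, 0L, alt = seq,
                                raw = raw))
    }
    v <- new_coding_variant(kind, s1, o1, s2, o2, raw = raw)
    if (kind %in% c("del", "dup")) v$ref <- seq
    if (kind == "delins") v$alt <- seq
    v$kind <- switch(kind, del = "deletion", dup = "duplication",
                     delins = "delins", ins = "insertion", kind)
    return(v)
  }
  stop("cannot parse HGVS description '", raw, "': offending token '",
       s, "'")
}

#' Format a coding variant as a canonical HGVS c. string
#'
#' Canonical output always carries the `c.` prefix and, per current HGVS
#' practice, omits the redundant deleted/duplicated sequence.
#'
#' @param v A `coding_variant`.
#' @return A character scalar.
#' @export
format_hgvs_c <- function(v) {
  stopifnot(inherits(v, "coding_variant"))
  p1 <- format_cpos(v$start, v$start_offset)
  p2 <- format_cpos(v$end, v$end_offset)
  rng <- if (p1 == p2) p1 else paste0(p1, "_", p2)
  body <- switch(v$kind,
    substitution = paste0(p1, v$ref, ">", v$alt),
    deletion = paste0(rng, "del"),
    duplication = paste0(rng, "dup"),
    insertion = paste0(rng, "ins", v$alt),
    delins = paste0(rng, "delins", v$alt),
    stop("unknown variant kind: ", v$kind))
  paste0("c.", body)
}

#' @export
print.coding_variant <- function(x, ...) {
  cat("<coding_variant> ", format_hgvs_c(x), " (", x$kind, ")\n", sep = "")
  invisible(x)
}

is_exonic <- function(v) v$start_offset == 0L && v$end_offset == 0L &&
  v$start >= 1L

# Nucleotides inserted minus deleted; frameshift iff not a multiple of 3.
net_length_change <- function(v) {
  switch(v$kind,
    substitution = 0L,
    deletion = -(v$end - v$start + 1L),
    duplication = v$end - v$start + 1L,
    insertion = nchar(v$alt),
    delins = nchar(v$alt) - (v$end - v$start + 1L))
}

#' 3'-normalize an insertion, deletion or duplication
#'
#' Shifts the variant toward the 3' end of the coding sequence as far as the
#' sequence permits (the HGVS most-3' rule), fills in the reference allele,
#' and rewrites an insertion that duplicates the immediately 5' sequence as a
#' duplication.  Idempotent.
#'
#' @param v A `coding_variant` of kind deletion, duplication or insertion,
#'   fully inside the CDS.
#' @param model A `gene_model` supplying the reference sequence.
#' @return The normalized `coding_variant`.
#' @export
normalize_indel <- function(v, model) {
  stopifnot(inherits(v, "coding_variant"))
  if (!v$kind %in% c("deletion", "duplication", "insertion"))
    stop("normalize_indel applies to deletions, duplications and insertions")
  if (!is_exonic(v))
    stop("normalize_indel requires a variant fully inside the CDS")
  cds <- model$cds
  L <- nchar(cds)
  if (v$end > L) stop("variant extends past the CDS end")
  if (v$kind == "deletion") {
    ref <- substr(cds, v$start, v$end)
    if (nzchar(v$ref) && v$ref != ref)
      stop("reference allele mismatch at c.", v$start, ": variant says '",
           v$ref, "' but the reference reads '", ref, "'")
    s <- v$start; e <- v$end
    while (e + 1L <= L && substr(cds, e + 1L, e + 1L) == substr(cds, s, s)) {
      s <- s + 1L; e <- e + 1L
    }
    out <- new_coding_variant("deletion", s, 0L, e, 0L,
                              ref = substr(cds, s, e), raw = v$raw)
    return(out)
  }
  # duplications and insertions: treat as an insertion of `seq` after `pos`
  if (v$kind == "duplication") {
    seq <- substr(cds, v$start, v$end)
    if (nzchar(v$ref) && v$ref != seq)
      stop("reference allele mismatch at c.", v$start, ": variant says '",
           v$ref, "' but the reference reads '", seq, "'")
    pos <- v$end
  } else {
    seq <- v$alt
    pos <- v$start
  }
  while (pos + 1L <= L && substr(cds, pos + 1L, pos + 1L) ==
           substr(seq, 1L, 1L)) {
    seq <- paste0(substr(seq, 2L, nchar(seq)), substr(seq, 1L, 1L))
    pos <- pos + 1L
  }
  k <- nchar(seq)
  if (pos >= k && substr(cds, pos - k + 1L, pos) == seq)
    new_coding_variant("duplication", pos - k + 1L, 0L, pos, 0L,
                       ref = seq, raw = v$raw)
  else
    new_coding_variant("insertion", pos, 0L, pos + 1L, 0L, alt = seq,
                       raw = v$raw)
}

#' Collapse a substitution onto the six-class mutational event spectrum
#'
#' Substitutions are reported strand-symmetrically (GC>AT, AT>GC, GC>TA,
#' GC>CG, AT>TA, AT>CG).  A C>T change with a 3' G neighbour -- or
#' equivalently a G>A change with a 5' C neighbour -- is flagged as a CpG
#' transition, the classical deamination hotspot context.  Indels map to
#' event class `"indel"` with no CpG flag.
#'
#' @param v A `coding_variant`.
#' @param model Optional `gene_model`; required to resolve CpG context for
#'   exonic substitutions (otherwise `cpg` is `NA`).
#' @return List with elements `event` and `cpg`.
#' @export
mutational_event <- function(v, model = NULL) {
  if (v$kind != "substitution") return(list(event = "indel", cpg = NA))
  key <- paste0(v$ref, ">", v$alt)
  event <- c("C>T" = "GC>AT", "G>A" = "GC>AT",
             "T>C" = "AT>GC", "A>G" = "AT>GC",
             "C>A" = "GC>TA", "G>T" = "GC>TA",
             "C>G" = "GC>CG", "G>C" = "GC>CG",
             "T>A" = "AT>TA", "A>T" = "AT>TA",
             "T>G" = "AT>CG", "A>C" = "AT>CG")[[key]]
  cpg <- NA
  if (!is.null(model) && is_exonic(v) && v$start <= nchar(model$cds)) {
    cds <- model$cds
    cpg <- FALSE
    if (v$ref == "C" && v$alt == "T" && v$start < nchar(cds))
      cpg <- substr(cds, v$start + 1L, v$start + 1L) == "G"
    if (v$ref == "G" && v$alt == "A" && v$start > 1L)
      cpg <- substr(cds, v$start - 1L, v$start - 1L) == "C"
  }
  list(event = event, cpg = cpg)
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter", X = "Xaa")

aa3 <- function(a) unname(AA3[strsplit(a, "")[[1L]]])

touches_splice_signal <- function(v) {
  so <- v$start_offset; eo <- v$end_offset
  (so != 0L && abs(so) <= 2L) || (eo != 0L && abs(eo) <= 2L) ||
    (so < 0L && eo == 0L) || (so == 0L && eo > 0L)
}

#' Classify a coding variant and annotate its consequence
#'
#' Assigns the variant class used throughout the cohort statistics:
#' intronic positions at the canonical +-1/+-2 splice offsets are `splice`,
#' deeper intronic positions `intronic_other`; exonic substitutions are
#' `missense`/`nonsense`/`synonymous` by codon translation; exonic indels
#' are `frameshift` when the net length change is not a multiple of 3, else
#' `inframe_indel`.  Exonic reference-allele mismatches are hard errors.
#'
#' @param v A `coding_variant` (or an HGVS string, parsed on the fly).
#' @param model A `gene_model`.
#' @param pathogenicity Optional consumed pathogenicity label
#'   (P/LP/VUS/LB/B); never computed.
#' @param normalize 3'-normalize indels before classification (default TRUE).
#' @return A `variant_annotation` list: `variant` (normalized), `hgvs_c`
#'   (canonical string), `var_class`, `codon`, `protein_hgvs`, `event`,
#'   `cpg`, `splice_signal` (catalogue row or `NULL`), `pathogenicity`.
#' @export
classify_variant <- function(v, model, pathogenicity = NA_character_,
                             normalize = TRUE) {
  if (is.character(v)) v <- parse_hgvs_c(v)
  stopifnot(inherits(v, "coding_variant"))
  ev <- mutational_event(v, model)
  ann <- list(variant = v, hgvs_c = NA_character_, var_class = NA_character_,
              codon = NA_integer_, protein_hgvs = NA_character_,
              event = ev$event, cpg = ev$cpg, splice_signal = NULL,
              pathogenicity = pathogenicity)
  class(ann) <- "variant_annotation"

  if (v$start_offset != 0L || v$end_offset != 0L) {
    # intronic (possibly boundary-crossing)
    if (touches_splice_signal(v)) {
      ann$var_class <- "splice"
      sig <- NULL
      if (v$start_offset < 0L)
        sig <- locate_splice_signal(model, v$start, max(v$start_offset, -2L))
      if (is.null(sig) && v$end_offset > 0L)
        sig <- locate_splice_signal(model, v$end, min(v$end_offset, 2L))
      if (is.null(sig) && v$start_offset > 0L)
        sig <- locate_splice_signal(model, v$start, min(v$start_offset, 2L))
      if (is.null(sig) && v$end_offset < 0L)
        sig <- locate_splice_signal(model, v$end, max(v$end_offset, -2L))
      if (is.null(sig))
        stop("intronic coordinate ", format_hgvs_c(v), " does not anchor a ",
             "known exon boundary of ", model$transcript_id)
      ann$splice_signal <- sig
    } else {
      anchors <- c(model$introns$donor_anchor, model$introns$acceptor_anchor)
      if (!(v$start %in% anchors || v$end %in% anchors))
        stop("intronic coordinate ", format_hgvs_c(v), " does not anchor a ",
             "known exon boundary of ", model$transcript_id)
      ann$var_class <- "intronic_other"
    }
    # reference check against intron sequence, where available; limited to
    # the canonical acceptor positions so that models carrying a synthetic
    # intron stand-in never contradict deep-intronic descriptions
    if (v$kind == "substitution" && v$start_offset %in% c(-1L, -2L)) {
      row <- model$introns[model$introns$acceptor_anchor == v$start, ]
      if (nrow(row) == 1L && !is.na(row$seq)) {
        Li <- nchar(row$seq)
        ref <- substr(row$seq, Li + v$start_offset + 1L, Li + v$start_offset + 1L)
        if (ref != v$ref)
          stop("reference allele mismatch at ", format_hgvs_c(v),
               ": intron reads '", ref, "'")
      }
    }
    ann$hgvs_c <- format_hgvs_c(v)
    return(ann)
  }

  # exonic
  L <- nchar(model$cds)
  if (v$start < 1L || v$end > L)
    stop("variant ", format_hgvs_c(v), " lies outside the CDS (1..", L, ")")
  if (v$kind == "substitution") {
    ref <- substr(model$cds, v$start, v$start)
    if (ref != v$ref)
      stop("reference allele mismatch at c.", v$start, ": variant says '",
           v$ref, "' but ", model$transcript_id, " reads '", ref, "'")
    cd <- cdna_to_codon(model, v$start)
    ann$codon <- cd$codon
    cstart <- 3L * (cd$codon - 1L) + 1L
    ref_codon <- substr(model$cds, cstart, cstart + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, cd$within, cd$within) <- v$alt
    ref_aa <- translate_dna(ref_codon)
    alt_aa <- translate_dna(alt_codon)
    if (alt_aa == ref_aa) {
      ann$var_class <- "synonymous"
      ann$protein_hgvs <- paste0("p.", aa3(ref_aa), cd$codon, "=")
    } else if (alt_aa == "*") {
      ann$var_class <- "nonsense"
      ann$protein_hgvs <- paste0("p.", aa3(ref_aa), cd$codon, "Ter")
    } else {
      ann$var_class <- "missense"
      ann$protein_hgvs <- paste0("p.", aa3(ref_aa), cd$codon, aa3(alt_aa))
    }
  } else {
    if (normalize && v$kind %in% c("deletion", "duplication", "insertion"))
      v <- normalize_indel(v, model)
    else if (v$kind == "delins") {
      ref <- substr(model$cds, v$start, v$end)
      if (nzchar(v$ref) && v$ref != ref)
        stop("reference allele mismatch at c.", v$start)
    }
    ann$variant <- v
    first_changed <- if (v$kind == "insertion") v$start + 1L
                     else if (v$kind == "duplication") min(v$end + 1L, L)
                     else v$start
    ann$codon <- cdna_to_codon(model, first_changed)$codon
    if (net_length_change(v) %% 3L != 0L) {
      ann$var_class <- "frameshift"
      cons <- translate_frameshift(v, model)
      ann$protein_hgvs <- cons$protein_hgvs
    } else {
      ann$var_class <- "inframe_indel"
      mut <- apply_variant_cds(model$cds, v)
      mutp <- translate_dna(mut)
      stop1 <- regexpr("*", mutp, fixed = TRUE)
      mutp <- if (stop1 > 0L) substr(mutp, 1L, stop1 - 1L) else mutp
      ann$protein_hgvs <- name_protein_change(model$protein, mutp)
    }
  }
  ann$hgvs_c <- format_hgvs_c(v)
  ann
}

#' @export
print.variant_annotation <- function(x, ...) {
  cat("<variant_annotation> ", x$hgvs_c, ": ", x$var_class, sep = "")
  if (!is.na(x$codon)) cat(", codon ", x$codon, sep = "")
  if (!is.na(x$protein_hgvs)) cat(", ", x$protein_hgvs, sep = "")
  cat("\n  event: ", x$event, if (isTRUE(x$cpg)) " (CpG)" else "", "\n",
      sep = "")
  if (!is.null(x$splice_signal))
    cat("  splice signal: ", x$splice_signal$label, "\n", sep = "")
  invisible(x)
}
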