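# Protein-level consequence prediction: frameshift translation, nonsense
# truncation, and splice-acceptor disruption with cryptic-acceptor
# (p53psi-type) isoform construction.

# Apply an exonic variant to a coding sequence string.
apply_variant_cds <- function(cds, v) {
  stopifnot(inherits(v, "coding_variant"), is_exonic(v))
  L <- nchar(cds)
  if (v$end > L) stop("variant extends past the CDS end")
  switch(v$kind,
    substitution = {
      out <- cds
      substr(out, v$start, v$start) <- v$alt
      out
    },
    deletion = paste0(substr(cds, 1L, v$start - 1L),
                      substr(cds, v$end + 1L, L)),
    insertion = paste0(substr(cds, 1L, v$start), v$alt,
                       substr(cds, v$start + 1L, L)),
    duplication = paste0(substr(cds, 1L, v$end),
                         substr(cds, v$start, v$end),
                         substr(cds, v$end + 1L, L)),
    delins = paste0(substr(cds, 1L, v$start - 1L), v$alt,
                    substr(cds, v$end + 1L, L)),
    stop("unknown variant kind: ", v$kind))
}

new_protein_consequence <- function(protein_hgvs, product, novel_cterm = "",
                                    truncation_codon = NA_integer_,
                                    isoform_tag = "truncated",
                                    no_stop = FALSE) {
  structure(list(protein_hgvs = protein_hgvs, product = product,
                 novel_cterm = novel_cterm,
                 truncation_codon = truncation_codon,
                 isoform_tag = isoform_tag, no_stop = no_stop),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("<protein_consequence> ", x$protein_hgvs, " [", x$isoform_tag, "]\n",
      "  product: ", nchar(x$product), " aa",
      if (nzchar(x$novel_cterm))
        paste0("; novel C-terminus: ", x$novel_cterm) else "",
      if (x$no_stop) "; no stop reached" else "", "\n", sep = "")
  invisible(x)
}

#' Name a protein change in HGVS p. nomenclature
#'
#' Derives the HGVS p. description from a reference and an observed protein
#' sequence (both without the terminal stop).  Handles identity,
#' substitutions, in-frame deletions/insertions/delins (maximally 3'-shifted
#' per the HGVS rule) and frameshift-type divergence (`p.XposYfsTerN`, where
#' `Ter N` counts the new stop from the first changed residue; `fsTer?` when
#' the observed sequence never reaches a stop).
#'
#' @param ref Reference protein sequence.
#' @param obs Observed protein sequence (truncated at its stop).
#' @param obs_has_stop Does `obs` end because a stop codon was reached
#'   (default TRUE)?
#' @param mode `"auto"` infers the change type from the two sequences;
#'   `"frameshift"` is used by callers that know the nucleotide-level edit
#'   shifted the frame, so protein-level coincidences are never misread as
#'   clean in-frame events.
#' @return Character scalar, e.g. `"p.Arg209LysfsTer6"`.
#' @export
name_protein_change <- function(ref, obs, obs_has_stop = TRUE,
                                mode = c("auto", "frameshift")) {
  mode <- match.arg(mode)
  if (identical(ref, obs)) return("p.=")
  r <- strsplit(ref, "")[[1L]]
  o <- strsplit(obs, "")[[1L]]
  nr <- length(r); no <- length(o)
  # longest common prefix
  lp <- 0L
  while (lp < min(nr, no) && r[lp + 1L] == o[lp + 1L]) lp <- lp + 1L
  # truncation: observed is a strict prefix of the reference
  if (no == lp && no < nr) {
    if (obs_has_stop)
      return(paste0("p.", AA3[[r[no + 1L]]], no + 1L, "Ter"))
    return(paste0("p.", AA3[[r[no + 1L]]], no + 1L, "TerfsTer?"))
  }
  if (mode == "auto") {
  # single-residue substitution
  if (nr == no) {
    diffs <- which(r != o)
    if (length(diffs) == 1L)
      return(paste0("p.", AA3[[r[diffs]]], diffs, AA3[[o[diffs]]]))
  }
  # longest common suffix compatible with the prefix
  ls <- 0L
  while (ls < min(nr, no) - lp && r[nr - ls] == o[no - ls]) ls <- ls + 1L
  tail_matches <- ls > 0L || (nr - lp == 0L) || (no - lp == 0L)
  if (nr != no && (lp + ls == min(nr, no)) && tail_matches) {
    if (no < nr) {                      # in-frame deletion
      ds <- lp + 1L; de <- nr - ls
      if (ds == de)
        return(paste0("p.", AA3[[r[ds]]], ds, "del"))
      return(paste0("p.", AA3[[r[ds]]], ds, "_", AA3[[r[de]]], de, "del"))
    }
    if (lp >= 1L && lp + 1L <= nr) {    # in-frame insertion (or dup)
      ins <- o[(lp + 1L):(no - ls)]
      return(paste0("p.", AA3[[r[lp]]], lp, "_", AA3[[r[lp + 1L]]], lp + 1L,
                    "ins", paste(AA3[ins], collapse = "")))
    }
  }
  if (nr == no && lp + ls < nr && sum(r != o) > 1L) {  # in-frame delins
    ds <- lp + 1L; de <- nr - ls
    return(paste0("p.", AA3[[r[ds]]], ds,
                  if (de > ds) paste0("_", AA3[[r[de]]], de) else "",
                  "delins", paste(AA3[o[ds:(no - ls)]], collapse = "")))
  }
  }
  # frameshift-type divergence
  pos <- lp + 1L
  refaa <- if (pos <= nr) r[pos] else "*"
  newaa <- if (pos <= no) o[pos] else "*"
  if (pos > no)                         # frameshift hit an immediate stop
    return(paste0("p.", AA3[[refaa]], pos, "Ter"))
  if (!obs_has_stop)
    return(paste0("p.", AA3[[refaa]], pos, AA3[[newaa]], "fsTer?"))
  paste0("p.", AA3[[refaa]], pos, AA3[[newaa]], "fsTer", no - pos + 2L)
}

#' Translate a frameshifting indel
#'
#' Applies the indel to the coding sequence, translates the shifted frame
#' from codon 1 to the first stop, and names the consequence per HGVS
#' (`p.XposYfsTerN`; if the first novel residue equals the reference the name
#' shifts to the first differing residue).  When the shifted frame reaches
#' the end of the available sequence without a stop, the consequence is
#' flagged `no_stop` and named `fsTer?`.
#'
#' @param v A `coding_variant`: an exonic indel whose net length change is
#'   not a multiple of 3.
#' @param model A `gene_model`.
#' @return A `protein_consequence`.
#' @export
translate_frameshift <- function(v, model) {
  if (is.character(v)) v <- parse_hgvs_c(v)
  if (!is_exonic(v) || v$kind == "substitution")
    stop("translate_frameshift requires an exonic indel")
  if (net_length_change(v) %% 3L == 0L)
    stop("variant is in-frame (net length change a multiple of 3)")
  mut <- apply_variant_cds(model$cds, v)
  mutp_full <- translate_dna(mut)
  stop_at <- regexpr("*", mutp_full, fixed = TRUE)
  no_stop <- stop_at < 0L
  product <- if (no_stop) mutp_full else substr(mutp_full, 1L, stop_at - 1L)
  name <- name_protein_change(model$protein, product,
                              obs_has_stop = !no_stop, mode = "frameshift")
  # novel C-terminus: residues after the last reference-matching position
  rp <- model$protein
  lp <- 0L
  while (lp < min(nchar(rp), nchar(product)) &&
         substr(rp, lp + 1L, lp + 1L) == substr(product, lp + 1L, lp + 1L))
    lp <- lp + 1L
  novel <- substr(product, lp + 1L, nchar(product))
  new_protein_consequence(name, product, novel_cterm = novel,
                          isoform_tag = "truncated", no_stop = no_stop)
}

#' Translate a nonsense substitution
#'
#' @param v A `coding_variant`: a substitution creating a stop codon.
#' @param model A `gene_model`.
#' @return A `protein_consequence` whose product is the reference protein
#'   truncated before the new stop.
#' @export
translate_nonsense <- function(v, model) {
  if (is.character(v)) v <- parse_hgvs_c(v)
  ann <- classify_variant(v, model)
  if (ann$var_class != "nonsense")
    stop("variant ", ann$hgvs_c, " is ", ann$var_class,
         ", not nonsense; classify_variant() routes consequences")
  product <- substr(model$protein, 1L, ann$codon - 1L)
  new_protein_consequence(ann$protein_hgvs, product,
                          truncation_codon = ann$codon,
                          isoform_tag = "truncated")
}

# First acceptor offset (retained length) whose AG dinucleotide survives in
# the (possibly mutated) intron; offset 0 is the canonical acceptor.
find_cryptic_acceptor <- function(intron_seq, max_offset = NULL) {
  L <- nchar(intron_seq)
  if (is.null(max_offset)) max_offset <- L - 4L
  for (off in 0:max_offset) {
    if (L - off - 1L < 1L) break
    if (substr(intron_seq, L - off - 1L, L - off) == "AG") return(off)
  }
  NA_integer_
}

#' Predict the outcome of a splice-acceptor variant
#'
#' Models the disruption of a canonical acceptor signal (intronic offset -1
#' or -2): splicing re-routes to a cryptic acceptor inside the intron, the
#' intronic 3' segment between the cryptic site and the exon is retained in
#' the transcript, and translation proceeds through the retained segment
#' into the downstream exon.  For TP53 intron 6 this reproduces the p53psi
#' isoform architecture: a 49-nt retention shifts the reading frame and
#' terminates at a stop near the start of exon 7.
#'
#' `fixed_offset` mode uses a stated retention length (default 49 nt, the
#' experimentally supported TP53 intron 6 site); `scan` mode selects the
#' nearest upstream AG dinucleotide that the variant has not itself
#' destroyed, ties broken toward the canonical site.
#'
#' @param v A `coding_variant` substitution at an acceptor signal (offset -1
#'   or -2) of an intron whose sequence is available.
#' @param model A `gene_model`.
#' @param cryptic_rule `"fixed_offset"` (default) or `"scan"`.
#' @param fixed_offset Retained length for `fixed_offset` mode (default 49).
#' @return A `splice_outcome`: `disrupted_signal` (catalogue row),
#'   `cryptic_site_offset`, `retained_sequence`, `predicted_transcript`, and
#'   `consequence` (a `protein_consequence`; tag `psi_like` when the
#'   retention shifts the frame to a stop inside the retained segment or
#'   early in the next exon).
#' @export
predict_splice_outcome <- function(v, model,
                                   cryptic_rule = c("fixed_offset", "scan"),
                                   fixed_offset = 49L) {
  cryptic_rule <- match.arg(cryptic_rule)
  if (is.character(v)) v <- parse_hgvs_c(v)
  if (v$kind != "substitution")
    stop("unsupported: only acceptor-signal substitutions are modelled")
  if (v$start_offset >= 1L)
    stop("unsupported: donor-site outcomes are not modelled")
  if (!(v$start_offset %in% c(-1L, -2L)))
    stop("variant does not hit a canonical acceptor signal (offset -1/-2)")
  row <- model$introns[model$introns$acceptor_anchor == v$start, ]
  if (nrow(row) != 1L)
    stop("position ", format_hgvs_c(v), " does not anchor an intron acceptor")
  if (is.na(row$seq))
    stop("capability error: no sequence available for intron ", row$intron,
         "; splice-consequence prediction needs the intron sequence")
  sig <- locate_splice_signal(model, v$start, v$start_offset)
  iseq <- row$seq
  Li <- nchar(iseq)
  ipos <- Li + v$start_offset + 1L        # intron coordinate of the variant
  ref <- substr(iseq, ipos, ipos)
  if (ref != v$ref)
    stop("reference allele mismatch at ", format_hgvs_c(v), ": intron reads '",
         ref, "'")
  substr(iseq, ipos, ipos) <- v$alt        # disrupt the acceptor

  if (cryptic_rule == "fixed_offset") {
    off <- as.integer(fixed_offset)
    if (off < 1L || Li - off - 1L < 1L)
      stop("fixed_offset must lie inside the intron")
    if (substr(iseq, Li - off - 1L, Li - off) != "AG")
      stop("no AG acceptor dinucleotide ", off, " nt upstream of the ",
           "canonical site in intron ", row$intron)
  } else {
    off <- find_cryptic_acceptor(iseq)
    if (is.na(off))
      stop("no surviving AG acceptor found in intron ", row$intron)
  }

  retained <- substr(iseq, Li - off + 1L, Li)
  anchor <- row$acceptor_anchor            # first base of the next exon
  cds <- model$cds
  tx <- paste0(substr(cds, 1L, anchor - 1L), retained,
               substr(cds, anchor, nchar(cds)))
  txp <- translate_dna(tx)
  stop_at <- regexpr("*", txp, fixed = TRUE)
  no_stop <- stop_at < 0L
  product <- if (no_stop) txp else substr(txp, 1L, stop_at - 1L)
  name <- name_protein_change(model$protein, product,
                              obs_has_stop = !no_stop,
                              mode = if (nchar(retained) %% 3L != 0L)
                                "frameshift" else "auto")
  tag <- if (identical(product, model$protein)) "full_length" else "truncated"
  if (!no_stop && nchar(retained) %% 3L != 0L) {
    stop_nt <- 3L * stop_at                # last nt of the stop codon in tx
    if (stop_nt <= (anchor - 1L) + off + 90L) tag <- "psi_like"
  }
  cons <- new_protein_consequence(name, product,
    novel_cterm = {
      lp <- 0L
      while (lp < min(nchar(model$protein), nchar(product)) &&
             substr(model$protein, lp + 1L, lp + 1L) ==
               substr(product, lp + 1L, lp + 1L)) lp <- lp + 1L
      substr(product, lp + 1L, nchar(product))
    },
    isoform_tag = tag, no_stop = no_stop)
  structure(list(disrupted_signal = sig, cryptic_site_offset = off,
                 retained_sequence = retained, predicted_transcript = tx,
                 consequence = cons),
            class = "splice_outcome")
}

#' @export
print.splice_outcome <- function(x, ...) {
  cat("<splice_outcome> ", x$disrupted_signal$label, ": cryptic acceptor ",
      x$cryptic_site_offset, " nt upstream; ", nchar(x$retained_sequence),
      " nt retained\n", sep = "")
  print(x$consequence)
  invisible(x)
}

#' Tabulate predicted consequences for a set of variants
#'
#' @param hgvs Character vector of HGVS c. descriptions.
#' @param model A `gene_model`.
#' @param file Optional path for a TSV export.
#' @param fasta Optional path for a FASTA of predicted protein products.
#' @return Data frame with columns `hgvs_c`, `var_class`, `protein_hgvs`,
#'   `isoform_tag`, `product_length`.
#' @export
consequence_table <- function(hgvs, model, file = NULL, fasta = NULL) {
  rows <- lapply(hgvs, function(h) {
    ann <- classify_variant(h, model)
    cons <- switch(ann$var_class,
      frameshift = translate_frameshift(ann$variant, model),
      nonsense = translate_nonsense(ann$variant, model),
      splice = tryCatch(predict_splice_outcome(ann$variant, model)$consequence,
                        error = function(e) NULL),
      NULL)
    data.frame(
      hgvs_c = ann$hgvs_c, var_class = ann$var_class,
      protein_hgvs = if (!is.null(cons)) cons$protein_hgvs else ann$protein_hgvs,
      isoform_tag = if (!is.null(cons)) cons$isoform_tag else "full_length",
      product_length = if (!is.null(cons)) nchar(cons$product)
                       else nchar(model$protein),
      product = if (!is.null(cons)) cons$product else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.table(out[, setdiff(names(out), "product")], file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    keep <- !is.na(out$product)
    if (any(keep)) {
      aa <- Biostrings::AAStringSet(out$product[keep])
      names(aa) <- paste0(out$hgvs_c[keep], " ", out$protein_hgvs[keep])
      Biostrings::writeXStringSet(aa, fasta)
    }
  }
  out[, setdiff(names(out), "product")]
}
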