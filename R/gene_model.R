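#' @import methods
#' @importFrom stats setNames
NULL

# Standard nuclear genetic code, as a fast lookup table.
CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

# Translate a DNA string into one-letter amino acids ("*" = stop).
# Trailing partial codons are dropped; unknown codons become "X".
translate_dna <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  aa <- CODON_TABLE[substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "",
                     fixed = TRUE)[[1L]]), collapse = "")
}

#' Construct a single-gene coding model
#'
#' Bundles the coding sequence, protein, coding-exon table and intron
#' catalogue of one transcript into a validated object.  All coordinates are
#' HGVS cDNA coordinates: position 1 is the A of the translation start,
#' intronic positions are written `anchor+offset` / `anchor-offset` relative
#' to the nearest exonic base, and 5' UTR positions are negative.
#'
#' @param cds Coding nucleotide sequence (A/C/G/T), a multiple of 3 ending in
#'   a stop codon with no internal stop.
#' @param exons Data frame with columns `exon`, `cdna_start`, `cdna_end`:
#'   contiguous, non-overlapping coding spans covering the CDS exactly.
#' @param transcript_id,protein_id Identifiers carried through to reports.
#' @param introns Optional data frame with columns `intron`, `donor_anchor`
#'   (last cDNA base of the upstream exon), `acceptor_anchor` (first cDNA
#'   base of the downstream exon) and optionally `seq` (intron sequence or
#'   `NA`).  When omitted, introns are derived from the exon boundaries and
#'   are sequence-absent.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(cds, exons, transcript_id = "transcript",
                       protein_id = "protein", introns = NULL) {
  cds <- toupper(gsub("\\s", "", cds))
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length (", nchar(cds), ") is not a multiple of 3")
  aa <- translate_dna(cds)
  if (substr(aa, nchar(aa), nchar(aa)) != "*")
    stop("CDS does not end in a stop codon")
  protein <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("\\*", protein)) stop("CDS contains an internal stop codon")

  exons <- as.data.frame(exons)
  need <- c("exon", "cdna_start", "cdna_end")
  if (!all(need %in% names(exons)))
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  exons <- exons[order(exons$cdna_start), need]
  if (exons$cdna_start[1L] != 1L)
    stop("first coding exon must start at cDNA position 1")
  if (any(exons$cdna_end < exons$cdna_start))
    stop("exon with cdna_end < cdna_start")
  if (nrow(exons) > 1L) {
    gaps <- exons$cdna_start[-1L] - exons$cdna_end[-nrow(exons)]
    if (any(gaps != 1L))
      stop("exon table has gaps or overlaps in cDNA space")
  }
  if (exons$cdna_end[nrow(exons)] != nchar(cds))
    stop("exon spans cover ", exons$cdna_end[nrow(exons)],
         " nt but the CDS is ", nchar(cds), " nt")

  if (is.null(introns)) {
    n <- nrow(exons)
    introns <- if (n > 1L)
      data.frame(intron = seq_len(n - 1L),
                 donor_anchor = exons$cdna_end[-n],
                 acceptor_anchor = exons$cdna_start[-1L],
                 seq = NA_character_)
    else
      data.frame(intron = integer(), donor_anchor = integer(),
                 acceptor_anchor = integer(), seq = character())
  } else {
    introns <- as.data.frame(introns)
    if (!all(c("intron", "donor_anchor", "acceptor_anchor") %in% names(introns)))
      stop("intron table must have columns intron, donor_anchor, acceptor_anchor")
    if (is.null(introns$seq)) introns$seq <- NA_character_
    introns <- introns[order(introns$intron), ]
    if (any(introns$acceptor_anchor - introns$donor_anchor != 1L &
            !(introns$donor_anchor < 0 & introns$acceptor_anchor ==
                introns$donor_anchor + 1L)))
      stop("intron anchors must bracket adjacent cDNA positions")
    coding <- introns$donor_anchor >= 1L
    if (!all(introns$donor_anchor[coding] %in% exons$cdna_end[-nrow(exons)]))
      stop("coding intron donor anchors must coincide with exon ends")
    has_seq <- !is.na(introns$seq)
    if (any(has_seq)) {
      bad <- has_seq & (substr(introns$seq, 1L, 2L) != "GT" |
                          substr(introns$seq, nchar(introns$seq) - 1L,
                                 nchar(introns$seq)) != "AG")
      if (any(bad))
        stop("intron sequence must start with GT and end with AG (intron ",
             paste(introns$intron[bad], collapse = ","), ")")
    }
  }

  structure(list(transcript_id = transcript_id, protein_id = protein_id,
                 cds = cds, protein = protein, exons = exons,
                 introns = introns),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$transcript_id, " / ", x$protein_id, "\n", sep = "")
  cat("  CDS: ", nchar(x$cds), " nt; protein: ", nchar(x$protein),
      " aa\n", sep = "")
  cat("  ", nrow(x$exons), " coding exons, ", nrow(x$introns), " introns (",
      sum(!is.na(x$introns$seq)), " with sequence)\n", sep = "")
  invisible(x)
}

#' Load a gene model from reference files
#'
#' @param cds_fasta FASTA file holding the coding sequence (first record).
#' @param exon_table TSV with columns `exon`, `cdna_start`, `cdna_end`
#'   (`#` comment lines ignored).
#' @param intron_table Optional TSV with columns `intron`, `donor_anchor`,
#'   `acceptor_anchor`, `sequence_file`; `sequence_file` entries are FASTA
#'   paths resolved relative to the table's directory (`NA` = sequence
#'   absent).
#' @inheritParams gene_model
#' @return A `gene_model`.
#' @export
load_gene_model <- function(cds_fasta, exon_table, intron_table = NULL,
                            transcript_id = "transcript",
                            protein_id = "protein") {
  cds <- as.character(Biostrings::readDNAStringSet(cds_fasta)[[1L]])
  exons <- utils::read.delim(exon_table, comment.char = "#",
                             stringsAsFactors = FALSE)
  introns <- NULL
  if (!is.null(intron_table)) {
    introns <- utils::read.delim(intron_table, comment.char = "#",
                                 stringsAsFactors = FALSE,
                                 na.strings = c("NA", ""))
    introns$seq <- NA_character_
    if ("sequence_file" %in% names(introns)) {
      for (i in which(!is.na(introns$sequence_file))) {
        path <- file.path(dirname(intron_table), introns$sequence_file[i])
        introns$seq[i] <-
          as.character(Biostrings::readDNAStringSet(path)[[1L]])
      }
    }
  }
  gene_model(cds, exons, transcript_id = transcript_id,
             protein_id = protein_id, introns = introns)
}

.tp53_cache <- new.env(parent = emptyenv())

#' The packaged TP53 model (NM_000546 / NP_000537)
#'
#' Builds the TP53 coding model from fixtures shipped with the package: the
#' 1,182-nt coding sequence of NM_000546 (393-residue protein NP_000537),
#' the ten-intron splice catalogue, and a synthetic intron 6 sequence that
#' carries the documented cryptic acceptor 49 nt upstream of the canonical
#' exon 7 junction.  Intron placements follow the 11-exon gene structure
#' (exon 1 non-coding; the exon 1/2 junction sits 28 nt upstream of the
#' start codon).  The object is cached for the session.
#'
#' @return A `gene_model` for TP53.
#' @export
tp53_model <- function() {
  if (is.null(.tp53_cache$model)) {
    ext <- function(f) system.file("extdata", f, package = "tp53cll",
                                   mustWork = TRUE)
    .tp53_cache$model <- load_gene_model(
      ext("NM_000546_cds.fa"), ext("tp53_exons.tsv"), ext("tp53_introns.tsv"),
      transcript_id = "NM_000546", protein_id = "NP_000537")
  }
  .tp53_cache$model
}

#' Map a cDNA position onto its codon
#'
#' @param model A `gene_model`.
#' @param pos Vector of exonic cDNA positions (1..CDS length).
#' @return Data frame with columns `pos`, `codon`, `within` (1..3).
#' @export
cdna_to_codon <- function(model, pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos)))
    stop("intronic or missing coordinate: codon mapping applies to exonic ",
         "positions only; use the splice-signal catalogue for intronic sites")
  if (any(pos < 1L | pos > nchar(model$cds)))
    stop("cDNA position outside the CDS (1..", nchar(model$cds), ")")
  data.frame(pos = pos, codon = (pos - 1L) %/% 3L + 1L,
             within = (pos - 1L) %% 3L + 1L)
}

#' Which coding exon contains a cDNA position
#' @inheritParams cdna_to_codon
#' @return Integer vector of exon numbers.
#' @export
exon_of <- function(model, pos) {
  pos <- as.integer(pos)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(model$exons)))
    out[pos >= model$exons$cdna_start[i] & pos <= model$exons$cdna_end[i]] <-
      model$exons$exon[i]
  out
}

format_cpos <- function(anchor, offset = 0L) {
  paste0(anchor, ifelse(offset > 0L, paste0("+", offset),
                        ifelse(offset < 0L, as.character(offset), "")))
}

#' Catalogue of canonical splice signals
#'
#' Each intron contributes one donor signal (positions +1, +2 after the last
#' base of the upstream exon) and one acceptor signal (positions -2, -1
#' before the first base of the downstream exon): a ten-intron gene yields
#' exactly twenty signals.
#'
#' @param model A `gene_model` with at least one intron.
#' @return Data frame with one row per signal: `intron`, `side`
#'   (donor/acceptor), `anchor`, `pos1`, `pos2` (HGVS coordinate strings) and
#'   `label`.
#' @export
splice_signal_catalogue <- function(model) {
  if (nrow(model$introns) < 1L) stop("model has no introns")
  key <- paste0("sigcat_", model$transcript_id, "_",
                paste(model$introns$donor_anchor, collapse = "."))
  if (!is.null(.tp53_cache[[key]])) return(.tp53_cache[[key]])
  don <- data.frame(intron = model$introns$intron, side = "donor",
                    anchor = model$introns$donor_anchor)
  don$pos1 <- format_cpos(don$anchor, 1L)
  don$pos2 <- format_cpos(don$anchor, 2L)
  acc <- data.frame(intron = model$introns$intron, side = "acceptor",
                    anchor = model$introns$acceptor_anchor)
  acc$pos1 <- format_cpos(acc$anchor, -2L)
  acc$pos2 <- format_cpos(acc$anchor, -1L)
  out <- rbind(don, acc)
  out <- out[order(out$intron, out$side == "acceptor"), ]
  out$label <- paste0("intron", out$intron, "_", out$side)
  rownames(out) <- NULL
  .tp53_cache[[key]] <- out
  out
}

# Find the splice signal covering an intronic coordinate (anchor, offset);
# NULL when the coordinate is not a canonical +-1/+-2 position.
locate_splice_signal <- function(model, anchor, offset) {
  cat_ <- splice_signal_catalogue(model)
  if (offset >= 1L && offset <= 2L)
    hit <- cat_[cat_$side == "donor" & cat_$anchor == anchor, ]
  else if (offset <= -1L && offset >= -2L)
    hit <- cat_[cat_$side == "acceptor" & cat_$anchor == anchor, ]
  else return(NULL)
  if (nrow(hit) == 0L) NULL else hit[1L, ]
}

#' Inverted repeats flanking a coding region
#'
#' Scans the CDS for inverted repeats (an arm followed, after a short spacer,
#' by its reverse complement) whose footprint overlaps a given cDNA range.
#' Such hairpin-forming contexts are a classical driver of small
#' insertion/deletion hotspots during replication.
#'
#' @param model A `gene_model`.
#' @param cdna_range Length-2 integer vector `(start, end)` within the CDS.
#' @param arm_len Arm length in nucleotides (>= 3).
#' @param max_spacer Maximum spacer length between the arms.
#' @return Data frame with columns `arm_start`, `arm2_start`, `spacer`,
#'   `arm`, `arm2` (zero rows when no repeat is found).
#' @export
inverted_repeat_context <- function(model, cdna_range, arm_len = 4L,
                                    max_spacer = 4L) {
  if (arm_len < 3L) stop("arm_len must be >= 3")
  cds <- model$cds
  L <- nchar(cds)
  if (length(cdna_range) != 2L || cdna_range[1L] < 1L || cdna_range[2L] > L ||
      cdna_range[1L] > cdna_range[2L])
    stop("cdna_range must lie within the CDS (1..", L, ")")
  hits <- list()
  for (i in seq_len(L - 2L * arm_len)) {
    arm <- substr(cds, i, i + arm_len - 1L)
    for (sp in 0:max_spacer) {
      j <- i + arm_len + sp
      if (j + arm_len - 1L > L) break
      arm2 <- substr(cds, j, j + arm_len - 1L)
      if (arm == revcomp(arm2)) {
        foot_end <- j + arm_len - 1L
        if (i <= cdna_range[2L] && foot_end >= cdna_range[1L])
          hits[[length(hits) + 1L]] <-
            data.frame(arm_start = i, arm2_start = j, spacer = sp,
                       arm = arm, arm2 = arm2)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(arm_start = integer(), arm2_start = integer(),
                      spacer = integer(), arm = character(),
                      arm2 = character()))
  do.call(rbind, hits)
}
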