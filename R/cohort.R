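# Cohort-level statistics: spectra, multiclonality, cumulated VAF, low-VAF
# census, hotspot enrichment, codon- and signal-level distributions.

COHORT_COLUMNS <- c("patient_id", "assay", "hgvs_c")
VAR_CLASSES <- c("missense", "frameshift", "inframe_indel", "nonsense",
                 "splice", "synonymous", "intronic_other")
EVENT_CLASSES <- c("GC>AT", "AT>GC", "GC>TA", "GC>CG", "AT>TA", "AT>CG")

#' Load and annotate a cohort variant table
#'
#' Reads the cohort schema (TSV or data frame) with columns `patient_id`,
#' `assay` (NGS|Sanger), `hgvs_c`, and optionally `vaf` (percent, NGS only),
#' `pathogenicity` (P/LP/VUS/LB/B), `del17p` (yes/no/unknown), `treatment`.
#' Every variant is parsed, 3'-normalized and classified against the gene
#' model; duplicate descriptions within a patient are collapsed; rows that
#' fail parsing, reference checks, or the VAF rules are reported in
#' `$rejected`, never silently dropped.  Patients appearing under both
#' assays are counted once, under NGS.
#'
#' @param x Path to a TSV or a data frame.
#' @param model A `gene_model` (default: the packaged TP53 model).
#' @param vaf_cutoff Reporting cutoff in percent for NGS records (default 1).
#' @param normalize 3'-normalize indels (default TRUE).
#' @return A `tp53_cohort`: list with `variants` (annotated data frame),
#'   `patients` (per-patient summary), `rejected`, `vaf_cutoff`.
#' @export
load_cohort <- function(x, model = tp53_model(), vaf_cutoff = 1,
                        normalize = TRUE) {
  tab <- if (is.character(x))
    utils::read.delim(x, comment.char = "#", stringsAsFactors = FALSE)
  else as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("cohort table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("vaf", "pathogenicity", "del17p", "treatment"))
    if (is.null(tab[[col]])) tab[[col]] <- NA
  tab$vaf <- suppressWarnings(as.numeric(tab$vaf))

  keep <- vector("list", nrow(tab))
  rej <- list()
  reject <- function(i, reason)
    rej[[length(rej) + 1L]] <<- data.frame(row = i, hgvs_c = tab$hgvs_c[i],
                                           reason = reason)
  for (i in seq_len(nrow(tab))) {
    assay <- toupper(trimws(tab$assay[i]))
    if (!assay %in% c("NGS", "SANGER")) { reject(i, "unknown assay"); next }
    assay <- if (assay == "NGS") "NGS" else "Sanger"
    vaf <- tab$vaf[i]
    if (assay == "NGS") {
      if (is.na(vaf)) { reject(i, "NGS record without VAF"); next }
      if (vaf <= 0 || vaf > 100) {
        reject(i, paste0("VAF ", vaf, " outside (0,100]")); next
      }
      if (vaf < vaf_cutoff) {
        reject(i, paste0("VAF below the ", vaf_cutoff, "% reporting cutoff"))
        next
      }
    } else vaf <- NA_real_
    ann <- tryCatch(
      classify_variant(tab$hgvs_c[i], model,
                       pathogenicity = as.character(tab$pathogenicity[i]),
                       normalize = normalize),
      error = function(e) e)
    if (inherits(ann, "error")) { reject(i, conditionMessage(ann)); next }
    keep[[i]] <- data.frame(
      patient_id = as.character(tab$patient_id[i]), assay = assay,
      hgvs_c = ann$hgvs_c, vaf = vaf,
      pathogenicity = as.character(tab$pathogenicity[i]),
      del17p = if (is.na(tab$del17p[i])) "unknown"
               else tolower(as.character(tab$del17p[i])),
      treatment = as.character(tab$treatment[i]),
      var_class = ann$var_class, codon = ann$codon,
      protein_hgvs = ann$protein_hgvs, event = ann$event,
      cpg = if (is.na(ann$cpg)) NA else ann$cpg,
      splice_label = if (is.null(ann$splice_signal)) NA_character_
                     else ann$splice_signal$label,
      splice_intron = if (is.null(ann$splice_signal)) NA_integer_
                      else ann$splice_signal$intron,
      splice_side = if (is.null(ann$splice_signal)) NA_character_
                    else ann$splice_signal$side,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, keep[!vapply(keep, is.null, logical(1L))])
  if (is.null(variants) || nrow(variants) == 0L)
    stop("no variant rows survived loading; see the rejected report")

  # a patient seen under both assays is kept under NGS only
  both <- intersect(variants$patient_id[variants$assay == "NGS"],
                    variants$patient_id[variants$assay == "Sanger"])
  if (length(both))
    variants <- variants[!(variants$assay == "Sanger" &
                             variants$patient_id %in% both), ]

  # collapse duplicate descriptions within a patient (keep highest VAF)
  o <- order(variants$patient_id, variants$hgvs_c, -xtfrm(variants$vaf),
             na.last = TRUE)
  variants <- variants[o, ]
  dup <- duplicated(variants[, c("patient_id", "hgvs_c")])
  n_collapsed <- sum(dup)
  variants <- variants[!dup, ]
  rownames(variants) <- NULL

  agg <- split(variants, variants$patient_id)
  patients <- do.call(rbind, lapply(agg, function(d) data.frame(
    patient_id = d$patient_id[1L], assay = d$assay[1L],
    del17p = d$del17p[1L], n_variants = nrow(d),
    cum_vaf = if (all(is.na(d$vaf))) NA_real_ else sum(d$vaf, na.rm = TRUE),
    stringsAsFactors = FALSE)))
  rownames(patients) <- NULL

  structure(list(variants = variants, patients = patients,
                 rejected = if (length(rej)) do.call(rbind, rej)
                            else data.frame(row = integer(),
                                            hgvs_c = character(),
                                            reason = character()),
                 n_collapsed = n_collapsed,
                 transcript_id = model$transcript_id,
                 vaf_cutoff = vaf_cutoff),
            class = "tp53_cohort")
}

#' @export
print.tp53_cohort <- function(x, ...) {
  cat("<tp53_cohort> ", nrow(x$variants), " variants in ",
      nrow(x$patients), " patients (", sum(x$patients$assay == "NGS"),
      " NGS / ", sum(x$patients$assay == "Sanger"), " Sanger)\n", sep = "")
  if (nrow(x$rejected)) cat("  ", nrow(x$rejected), " row(s) rejected\n",
                            sep = "")
  invisible(x)
}

ngs_subset <- function(cohort) {
  list(variants = cohort$variants[cohort$variants$assay == "NGS", ],
       patients = cohort$patients[cohort$patients$assay == "NGS", ])
}

#' Variant-class spectrum
#'
#' Proportions of each variant class over all variants (the denominator is
#' the variant count, not the patient count).
#'
#' @param cohort A `tp53_cohort`.
#' @return Data frame with `var_class`, `n`, `proportion`.
#' @export
class_spectrum <- function(cohort) {
  v <- cohort$variants
  if (nrow(v) == 0L) stop("empty cohort")
  n <- table(factor(v$var_class, levels = VAR_CLASSES))
  out <- data.frame(var_class = names(n), n = as.integer(n))
  out$proportion <- out$n / sum(out$n)
  out
}

#' Six-class mutational-event spectrum
#'
#' Proportions over substitutions only (indels excluded from the
#' denominator), plus the fraction of GC>AT transitions in CpG context.
#'
#' @param cohort A `tp53_cohort`.
#' @return Data frame with `event`, `n`, `proportion`, `n_cpg`.
#' @export
event_spectrum <- function(cohort) {
  v <- cohort$variants[cohort$variants$event %in% EVENT_CLASSES, ]
  if (nrow(v) == 0L) stop("cohort contains no substitutions")
  n <- table(factor(v$event, levels = EVENT_CLASSES))
  ncpg <- vapply(EVENT_CLASSES, function(e)
    sum(v$event == e & v$cpg %in% TRUE), integer(1L))
  out <- data.frame(event = EVENT_CLASSES, n = as.integer(n),
                    proportion = as.integer(n) / sum(n),
                    n_cpg = ncpg)
  rownames(out) <- NULL
  out
}

#' Per-patient multiclonality classes
#'
#' Labels each patient by the count of distinct variants: SM (one), DM
#' (two), MM3 (three), MM4plus (more than three).  By default only the NGS
#' subset is used, since Sanger sequencing cannot resolve low-VAF clones.
#'
#' @param cohort A `tp53_cohort`.
#' @param assay `"NGS"` (default) or `"all"`.
#' @return List: `per_patient` (patient_id, n_variants, label), `histogram`
#'   (label, n), `n_patients`, `n_multi`, `range` of per-patient counts
#'   among multi-mutated patients.
#' @export
multiclonality <- function(cohort, assay = c("NGS", "all")) {
  assay <- match.arg(assay)
  p <- if (assay == "NGS") ngs_subset(cohort)$patients else cohort$patients
  if (nrow(p) == 0L) stop("no patients in the selected assay subset")
  lab <- cut(p$n_variants, breaks = c(0, 1, 2, 3, Inf),
             labels = c("SM", "DM", "MM3", "MM4plus"))
  hist <- as.data.frame(table(label = lab), responseName = "n")
  multi <- p$n_variants[p$n_variants >= 2L]
  list(per_patient = data.frame(patient_id = p$patient_id,
                                n_variants = p$n_variants,
                                label = as.character(lab)),
       histogram = hist,
       n_patients = nrow(p), n_multi = length(multi),
       range = if (length(multi)) range(multi) else c(NA_integer_,
                                                      NA_integer_))
}

#' Cumulated VAF per patient
#'
#' Sums the per-variant VAFs of each NGS patient.  A sum above 100% would
#' imply overlapping clones on the same allele complement; in CLL cohorts
#' the sum stays at or below 100%, consistent with variants residing on
#' different alleles or in independent subclones.
#'
#' @param cohort A `tp53_cohort`.
#' @return Data frame with `patient_id`, `n_variants`, `cum_vaf`,
#'   `exceeds_100`.
#' @export
cumulated_vaf <- function(cohort) {
  ng <- ngs_subset(cohort)
  if (nrow(ng$patients) == 0L) stop("no NGS patients")
  if (anyNA(ng$variants$vaf))
    stop("NGS variants with absent VAF; cannot cumulate")
  data.frame(patient_id = ng$patients$patient_id,
             n_variants = ng$patients$n_variants,
             cum_vaf = ng$patients$cum_vaf,
             exceeds_100 = ng$patients$cum_vaf > 100)
}

#' Census of patients and variants in a low-VAF band
#'
#' Counts NGS patients with at least one variant whose VAF falls in
#' `[lo, hi]` (default the 1--5% band that conventional Sanger sequencing
#' cannot resolve), split into single-mutated (SM) and multi-mutated
#' patients, alongside the variant-level counts in the band.
#'
#' @param cohort A `tp53_cohort`.
#' @param lo,hi Band bounds in percent, inclusive; `lo < hi` required.
#' @return List of counts: `n_patients`, `n_patients_single`,
#'   `n_patients_multi`, `n_variants`, `n_variants_single`,
#'   `n_variants_multi`.
#' @export
low_vaf_census <- function(cohort, lo = 1, hi = 5) {
  if (lo >= hi) stop("lo must be < hi")
  ng <- ngs_subset(cohort)
  v <- ng$variants
  in_band <- !is.na(v$vaf) & v$vaf >= lo & v$vaf <= hi
  nv <- ng$patients$n_variants[match(v$patient_id, ng$patients$patient_id)]
  pat_in <- unique(v$patient_id[in_band])
  pat_n <- ng$patients$n_variants[match(pat_in, ng$patients$patient_id)]
  list(n_patients = length(pat_in),
       n_patients_single = sum(pat_n == 1L),
       n_patients_multi = sum(pat_n >= 2L),
       n_variants = sum(in_band),
       n_variants_single = sum(in_band & nv == 1L),
       n_variants_multi = sum(in_band & nv >= 2L))
}

#' Hotspot enrichment between two cohorts
#'
#' Tests a 2x2 table (focal variant vs all other variants, cohort A vs
#' cohort B) with a chi-square test without continuity correction, falling
#' back to Fisher's exact test when any expected cell is below 5.  The odds
#' ratio uses the Haldane 0.5 correction when a cell is zero.
#'
#' @param focal_a,total_a Focal and total variant counts in cohort A.
#' @param focal_b,total_b Focal and total variant counts in cohort B.
#' @param method `"auto"` (default), `"chi2"` or `"fisher"`.
#' @return List with `table`, `statistic`, `p_value`, `odds_ratio`,
#'   `method`.
#' @export
hotspot_enrichment <- function(focal_a, total_a, focal_b, total_b,
                               method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  if (total_a <= 0 || total_b <= 0) stop("zero total count")
  if (focal_a < 0 || focal_b < 0 || focal_a > total_a || focal_b > total_b)
    stop("focal counts must lie in [0, total]")
  tab <- matrix(c(focal_a, total_a - focal_a,
                  focal_b, total_b - focal_b),
                nrow = 2L, byrow = TRUE,
                dimnames = list(cohort = c("A", "B"),
                                variant = c("focal", "other")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use <- method
  if (method == "auto") use <- if (any(expected < 5)) "fisher" else "chi2"
  if (use == "chi2") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- stats::fisher.test(tab)
    statistic <- NA_real_
    p <- ht$p.value
  }
  t2 <- tab
  if (any(tab == 0)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(table = tab, statistic = statistic, p_value = p, odds_ratio = or,
       method = use)
}

#' Codon distribution of frameshift variants
#'
#' The codon of a frameshift is the codon containing the first
#' deleted/inserted base after 3' normalization; frequencies are over
#' frameshift variants.
#'
#' @param cohort A `tp53_cohort`.
#' @return Data frame with `codon`, `hgvs_c` of the modal description per
#'   codon, `n`, `proportion`.
#' @export
frameshift_codon_distribution <- function(cohort) {
  v <- cohort$variants[cohort$variants$var_class == "frameshift", ]
  if (nrow(v) == 0L) stop("cohort contains no frameshift variants")
  sp <- split(v, v$codon)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    codon = d$codon[1L],
    hgvs_c = names(sort(table(d$hgvs_c), decreasing = TRUE))[1L],
    n = nrow(d))))
  out$proportion <- out$n / sum(out$n)
  out <- out[order(-out$n, out$codon), ]
  rownames(out) <- NULL
  out
}

#' Distribution of splice variants over the signal catalogue
#'
#' Frequencies over splice variants, pooled per signal (the two positions of
#' a signal together) and reported separately per position.
#'
#' @param cohort A `tp53_cohort`.
#' @param model The `gene_model` whose catalogue defines the signals.
#' @return List with `by_signal` (label, n, proportion over splice variants)
#'   and `by_position` (HGVS position string, n, proportion).
#' @export
splice_signal_distribution <- function(cohort, model = tp53_model()) {
  v <- cohort$variants[cohort$variants$var_class == "splice", ]
  if (nrow(v) == 0L) stop("cohort contains no splice variants")
  cat_ <- splice_signal_catalogue(model)
  n <- vapply(cat_$label, function(l) sum(v$splice_label %in% l), integer(1L))
  by_signal <- data.frame(label = cat_$label, intron = cat_$intron,
                          side = cat_$side, n = n,
                          proportion = n / nrow(v))
  rownames(by_signal) <- NULL
  pos <- sub("^c\\.", "", sub("[ACGT]>[ACGT]$", "", v$hgvs_c))
  tp <- table(pos)
  by_position <- data.frame(position = names(tp), n = as.integer(tp),
                            proportion = as.integer(tp) / nrow(v))
  by_position <- by_position[order(-by_position$n), ]
  rownames(by_position) <- NULL
  list(by_signal = by_signal, by_position = by_position)
}

#' Compare VAF distributions between variant groups
#'
#' Two-sided Wilcoxon rank-sum tests on per-variant VAFs between every pair
#' of groups, grouping either by the consumed pathogenicity label or by
#' variant recurrence (how often the identical description occurs in the
#' cohort: 1, 2-5, >5).  Groups with fewer than `min_n` observations are
#' skipped with a notice.
#'
#' @param cohort A `tp53_cohort`.
#' @param by `"pathogenicity"` or `"recurrence"`.
#' @param min_n Minimum group size (default 2).
#' @return Data frame of pairwise results (`group1`, `group2`, `n1`, `n2`,
#'   `median1`, `median2`, `p_value`); skipped groups in
#'   `attr(, "skipped")`.
#' @export
vaf_group_comparison <- function(cohort, by = c("pathogenicity",
                                                "recurrence"),
                                 min_n = 2L) {
  by <- match.arg(by)
  v <- ngs_subset(cohort)$variants
  v <- v[!is.na(v$vaf), ]
  if (by == "pathogenicity") {
    v <- v[!is.na(v$pathogenicity) & v$pathogenicity != "NA", ]
    g <- v$pathogenicity
  } else {
    rec <- table(v$hgvs_c)[v$hgvs_c]
    g <- cut(as.integer(rec), breaks = c(0, 1, 5, Inf),
             labels = c("1", "2-5", ">5"))
    g <- as.character(g)
  }
  sizes <- table(g)
  skipped <- names(sizes)[sizes < min_n]
  groups <- setdiff(names(sizes), skipped)
  if (length(groups) < 2L) stop("fewer than two groups with >= ", min_n,
                                " observations")
  pairs <- utils::combn(sort(groups), 2L)
  out <- do.call(rbind, apply(pairs, 2L, function(pr) {
    x <- v$vaf[g == pr[1L]]; y <- v$vaf[g == pr[2L]]
    p <- if (length(unique(c(x, y))) == 1L) 1   # complete ties
         else suppressWarnings(stats::wilcox.test(x, y,
                                                  exact = FALSE)$p.value)
    data.frame(group1 = pr[1L], group2 = pr[2L], n1 = length(x),
               n2 = length(y), median1 = stats::median(x),
               median2 = stats::median(y), p_value = p)
  }))
  attr(out, "skipped") <- skipped
  out
}

#' Assemble the cohort summary report
#'
#' @param cohort A `tp53_cohort`.
#' @return List of the headline tables: class spectrum, event spectrum,
#'   multiclonality histogram, cumulated VAF, low-VAF census.
#' @export
cohort_report <- function(cohort) {
  list(class_spectrum = class_spectrum(cohort),
       event_spectrum = event_spectrum(cohort),
       multiclonality = multiclonality(cohort)$histogram,
       cumulated_vaf = cumulated_vaf(cohort),
       low_vaf_census = low_vaf_census(cohort))
}
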