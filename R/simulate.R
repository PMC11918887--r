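# Seeded simulators: cohorts with hotspot-weighted variant draws and
# clone-constrained VAFs, reads carrying variants in cis or trans, and SNP
# profiles with and without copy-neutral LOH.  All randomness flows from a
# single seed; the caller's RNG state is preserved.

local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default cohort-generation parameters
#'
#' The defaults encode the mutational structure of a TP53-mutated CLL
#' cohort: 511 of 683 patients assayed by NGS (the rest Sanger), per-variant
#' class mixture 73/11/2/6/8 percent
#' (missense/frameshift/inframe/nonsense/splice), NGS multiclonality weights
#' SM/DM/MM3/MM4plus of 351/81/41/38 out of 511 (31% multi-mutated,
#' MM4plus counts drawn on 4..14), the CLL hotspot masses (c.626_627del at
#' 16% of frameshifts, codon-210 frameshifts at 4%, the three c.673-2
#' acceptor substitutions jointly at 22% of splice variants in equal parts,
#' c.637C>T and c.586C>T as the leading nonsense variants, CpG
#' missense hotspots at codons 175/248/273 plus the treatment-associated
#' codon 234), a substitution-event mixture with roughly 20% AT>GC
#' transitions, and log-uniform VAF draws (2--90% for single-mutated,
#' 1.2--30% per variant for multi-mutated patients) capped so that no
#' patient's cumulated VAF exceeds 100%.
#'
#' @return Named list of parameters consumed by [simulate_cohort()].
#' @export
default_cohort_params <- function() {
  list(
    n_ngs = 511L,
    class_mix = c(missense = 0.73, frameshift = 0.11, inframe_indel = 0.02,
                  nonsense = 0.06, splice = 0.08),
    multiclonality_weights = c(SM = 351, DM = 81, MM3 = 41, MM4plus = 38) /
      511,
    mm4_range = 4:14,
    mm4_decay = 0.55,
    # missense: probability of drawing from the hotspot menu, and the menu
    missense_hotspot_prob = 0.35,
    missense_hotspots = c(
      "c.524G>A" = 0.16,  # p.Arg175His (CpG)
      "c.743G>A" = 0.12,  # p.Arg248Gln (CpG)
      "c.742C>T" = 0.08,  # p.Arg248Trp (CpG)
      "c.818G>A" = 0.12,  # p.Arg273His (CpG)
      "c.817C>T" = 0.08,  # p.Arg273Cys (CpG)
      "c.844C>T" = 0.06,  # p.Arg282Trp (CpG)
      "c.659A>G" = 0.08,  # p.Tyr220Cys
      "c.700T>C" = 0.12,  # p.Tyr234His (CLL/alkylating-treatment hotspot)
      "c.701A>G" = 0.06,  # p.Tyr234Cys
      "c.701A>C" = 0.02,  # p.Tyr234Ser
      "c.733G>A" = 0.10), # p.Gly245Ser (CpG)
    # event mixture for non-hotspot missense draws (CLL-like: high GC>AT,
    # ~20% AT>GC)
    event_mix = c("GC>AT" = 0.40, "AT>GC" = 0.22, "GC>TA" = 0.10,
                  "GC>CG" = 0.09, "AT>TA" = 0.10, "AT>CG" = 0.09),
    cpg_enrichment = 0.60,   # fraction of random GC>AT draws forced onto CpG
    fs_hotspot_626 = 0.16,   # c.626_627del share of frameshifts
    fs_hotspot_210 = 0.04,   # codon-210 frameshift share (c.629del)
    splice_hotspot_673 = 0.22,  # c.673-2A>G/T/C jointly, equal parts
    nonsense_hotspots = c("c.637C>T" = 0.30, "c.586C>T" = 0.20),
    vaf_single = c(2, 90),   # log-uniform bounds, percent
    vaf_multi = c(1.2, 30),
    cnloh_prob = 0.025,      # single-mutated NGS patients with CN-LOH
    cnloh_vaf = c(52, 98),
    del17p_known_prob = 0.41,
    del17p_yes_prob = 0.35,
    pathogenicity_mix = c(P = 0.60, LP = 0.22, VUS = 0.18),
    sanger_second_prob = 0.14)
}

# --- class-conditional variant draws --------------------------------------

draw_missense <- function(model, par) {
  if (stats::runif(1L) < par$missense_hotspot_prob)
    return(sample(names(par$missense_hotspots), 1L,
                  prob = par$missense_hotspots))
  cds <- model$cds
  L <- nchar(cds) - 3L          # keep the stop codon untouched
  pur <- c(A = "G", G = "A"); pyr <- c(C = "T", T = "C")
  repeat {
    ev <- sample(names(par$event_mix), 1L, prob = par$event_mix)
    want_cpg <- ev == "GC>AT" && stats::runif(1L) < par$cpg_enrichment
    pos <- sample.int(L, 1L)
    ref <- substr(cds, pos, pos)
    alt <- switch(ev,
      "GC>AT" = if (ref %in% c("C", "G")) c(C = "T", G = "A")[[ref]] else NA,
      "AT>GC" = if (ref %in% c("A", "T")) c(A = "G", T = "C")[[ref]] else NA,
      "GC>TA" = if (ref %in% c("C", "G")) c(C = "A", G = "T")[[ref]] else NA,
      "GC>CG" = if (ref %in% c("C", "G")) c(C = "G", G = "C")[[ref]] else NA,
      "AT>TA" = if (ref %in% c("A", "T")) c(A = "T", T = "A")[[ref]] else NA,
      "AT>CG" = if (ref %in% c("A", "T")) c(A = "C", T = "G")[[ref]] else NA)
    if (is.na(alt)) next
    if (want_cpg) {
      is_cpg <- (ref == "C" && substr(cds, pos + 1L, pos + 1L) == "G") ||
        (ref == "G" && pos > 1L && substr(cds, pos - 1L, pos - 1L) == "C")
      if (!is_cpg) next
    }
    h <- paste0("c.", pos, ref, ">", alt)
    ann <- classify_variant(h, model)
    if (ann$var_class == "missense") return(h)
  }
}

draw_frameshift <- function(model, par) {
  u <- stats::runif(1L)
  if (u < par$fs_hotspot_626) return("c.626_627del")
  if (u < par$fs_hotspot_626 + par$fs_hotspot_210) return("c.629del")
  cds <- model$cds
  repeat {
    len <- sample(c(1L, 2L, 4L), 1L, prob = c(0.6, 0.3, 0.1))
    kind <- sample(c("del", "dup"), 1L, prob = c(0.75, 0.25))
    pos <- sample.int(nchar(cds) - len - 3L, 1L)
    h <- if (len == 1L) paste0("c.", pos, kind)
         else paste0("c.", pos, "_", pos + len - 1L, kind)
    ann <- tryCatch(classify_variant(h, model), error = function(e) NULL)
    if (!is.null(ann) && ann$var_class == "frameshift" &&
        !ann$hgvs_c %in% c("c.626_627del", "c.629del"))
      return(ann$hgvs_c)
  }
}

draw_splice <- function(model, par) {
  if (stats::runif(1L) < par$splice_hotspot_673)
    return(sample(c("c.673-2A>G", "c.673-2A>T", "c.673-2A>C"), 1L))
  cat_ <- splice_signal_catalogue(model)
  repeat {
    row <- cat_[sample.int(nrow(cat_), 1L), ]
    pos <- sample(c(row$pos1, row$pos2), 1L)
    # canonical motif gives the reference base: GT donor, AG acceptor
    off <- as.integer(sub("^-?\\d+", "", pos))
    ref <- if (row$side == "donor") c("G", "T")[off] else c("A", "G")[off + 3L]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    h <- paste0("c.", pos, ref, ">", alt)
    if (!grepl("^c\\.673-2", h)) return(h)
  }
}

draw_nonsense <- function(model, par) {
  u <- stats::runif(1L)
  cum <- cumsum(par$nonsense_hotspots)
  for (i in seq_along(cum)) if (u < cum[i])
    return(names(par$nonsense_hotspots)[i])
  cds <- model$cds
  sites <- stop_gain_sites(model)
  h <- sites[sample.int(length(sites), 1L)]
  h
}

# all substitutions that create a stop codon (cached per model)
stop_gain_sites <- function(model) {
  key <- paste0("stops_", model$transcript_id, "_", nchar(model$cds))
  if (!is.null(.tp53_cache[[key]])) return(.tp53_cache[[key]])
  cds <- model$cds
  out <- character()
  for (cod in seq_len(nchar(cds) %/% 3L - 1L)) {
    s <- 3L * (cod - 1L) + 1L
    ref_codon <- substr(cds, s, s + 2L)
    if (translate_dna(ref_codon) == "*") next
    for (w in 1:3) for (alt in setdiff(c("A", "C", "G", "T"),
                                       substr(ref_codon, w, w))) {
      codon <- ref_codon
      substr(codon, w, w) <- alt
      if (translate_dna(codon) == "*")
        out <- c(out, paste0("c.", s + w - 1L,
                             substr(ref_codon, w, w), ">", alt))
    }
  }
  .tp53_cache[[key]] <- out
  out
}

draw_inframe <- function(model, par) {
  cds <- model$cds
  repeat {
    pos <- sample.int(nchar(cds) - 9L, 1L)
    h <- paste0("c.", pos, "_", pos + 2L, "del")
    ann <- tryCatch(classify_variant(h, model), error = function(e) NULL)
    if (!is.null(ann) && ann$var_class == "inframe_indel") return(ann$hgvs_c)
  }
}

draw_variant <- function(class, model, par) {
  switch(class,
    missense = draw_missense(model, par),
    frameshift = draw_frameshift(model, par),
    inframe_indel = draw_inframe(model, par),
    nonsense = draw_nonsense(model, par),
    splice = draw_splice(model, par),
    stop("unknown class: ", class))
}

#' Simulate a TP53-mutated cohort
#'
#' Draws a cohort of single- and multi-mutated patients under the default
#' (or supplied) study conditions: hotspot-weighted variant draws per class,
#' per-patient multiclonality, clone-constrained VAFs whose per-patient sum
#' never exceeds 100% (the wild-type residual makes up the remainder), a
#' small fraction of single-mutated copy-neutral-LOH patients with VAF above
#' 50%, and a Sanger subset without VAFs.  Reproducible: the same seed gives
#' byte-identical tables.
#'
#' @param n_patients Total cohort size (default 683).
#' @param seed Integer seed for all randomness.
#' @param params Parameter list, see [default_cohort_params()].
#' @param model A `gene_model` (default: packaged TP53).
#' @return List with `table` (the cohort TSV schema: patient_id, assay,
#'   hgvs_c, vaf, pathogenicity, del17p, treatment) and `truth` (per-patient
#'   generating record: multiclonality label, CN-LOH flag, clone VAFs).
#' @export
simulate_cohort <- function(n_patients = 683L, seed = 1L,
                            params = default_cohort_params(),
                            model = tp53_model()) {
  par <- utils::modifyList(default_cohort_params(), params)
  if (any(par$class_mix < 0) || abs(sum(par$class_mix) - 1) > 1e-8)
    stop("class_mix must be a probability distribution")
  if (any(par$multiclonality_weights < 0) ||
      abs(sum(par$multiclonality_weights) - 1) > 0.01)
    stop("multiclonality weights must be a probability distribution")
  par$multiclonality_weights <-
    par$multiclonality_weights / sum(par$multiclonality_weights)
  n_ngs <- min(par$n_ngs, n_patients)
  local_seed(seed, {
    rows <- list(); truth <- list()
    mm4_prob <- par$mm4_decay^(seq_along(par$mm4_range) - 1L)
    draw_patient_variants <- function(k) {
      out <- character(0L)
      while (length(out) < k) {
        cls <- sample(names(par$class_mix), 1L, prob = par$class_mix)
        h <- draw_variant(cls, model, par)
        if (!h %in% out) out <- c(out, h)
      }
      out
    }
    logu <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
    for (i in seq_len(n_patients)) {
      is_ngs <- i <= n_ngs
      pid <- sprintf("%s_%03d", if (is_ngs) "NGS" else "SGR", i)
      if (is_ngs) {
        lab <- sample(names(par$multiclonality_weights), 1L,
                      prob = par$multiclonality_weights)
        k <- switch(lab, SM = 1L, DM = 2L, MM3 = 3L,
                    MM4plus = sample(par$mm4_range, 1L, prob = mm4_prob))
        hg <- draw_patient_variants(k)
        cnloh <- FALSE
        if (k == 1L && stats::runif(1L) < par$cnloh_prob) {
          cnloh <- TRUE
          vaf <- stats::runif(1L, par$cnloh_vaf[1L], par$cnloh_vaf[2L])
          del17p <- "no"
        } else {
          vaf <- if (k == 1L) logu(1L, par$vaf_single[1L], par$vaf_single[2L])
                 else logu(k, par$vaf_multi[1L], par$vaf_multi[2L])
          if (sum(vaf) > 100) vaf <- vaf * 99.5 / sum(vaf)
          del17p <- if (stats::runif(1L) < par$del17p_known_prob) {
            if (stats::runif(1L) < par$del17p_yes_prob) "yes" else "no"
          } else "unknown"
        }
        vaf <- round(pmax(vaf, 1.0), 1L)
        rows[[i]] <- data.frame(
          patient_id = pid, assay = "NGS", hgvs_c = hg, vaf = vaf,
          pathogenicity = sample(names(par$pathogenicity_mix), k, TRUE,
                                 prob = par$pathogenicity_mix),
          del17p = del17p, treatment = NA_character_,
          stringsAsFactors = FALSE)
        truth[[pid]] <- list(label = lab, n_variants = k, cnloh = cnloh,
                             del17p = del17p, clone_vafs = vaf)
      } else {
        k <- if (stats::runif(1L) < par$sanger_second_prob) 2L else 1L
        hg <- draw_patient_variants(k)
        rows[[i]] <- data.frame(
          patient_id = pid, assay = "Sanger", hgvs_c = hg, vaf = NA_real_,
          pathogenicity = sample(names(par$pathogenicity_mix), k, TRUE,
                                 prob = par$pathogenicity_mix),
          del17p = "unknown", treatment = NA_character_,
          stringsAsFactors = FALSE)
        truth[[pid]] <- list(label = if (k == 1L) "SM" else "DM",
                             n_variants = k, cnloh = FALSE,
                             del17p = "unknown", clone_vafs = NULL)
      }
    }
    list(table = do.call(rbind, rows), truth = truth)
  })
}

# --- clonal architectures and read simulation -----------------------------

#' Construct a clonal architecture
#'
#' Describes one patient's tumor for read- and SNP-level simulation: a list
#' of subclones, each with a cell fraction (percent), a set of variants and
#' an allele assignment (1 or 2) per variant -- variants on the same allele
#' of the same clone are in cis, all other pairs in trans.  Clone fractions
#' must sum to at most 100; the remainder is wild-type.
#'
#' @param clones List of lists with elements `fraction`, `variants`
#'   (character), `alleles` (integer vector, same length; defaults to
#'   allele 1).
#' @param het_snps Character vector of germline-heterozygous SNP ids.
#' @param cnloh Does the (first) clone carry copy-neutral LOH?
#' @param del17p del(17p) status string.
#' @param patient_id Identifier.
#' @return A `clonal_architecture`.
#' @export
clonal_architecture <- function(clones, het_snps = character(),
                                cnloh = FALSE, del17p = "no",
                                patient_id = "P1") {
  for (i in seq_along(clones)) {
    cl <- clones[[i]]
    if (is.null(cl$fraction) || cl$fraction <= 0)
      stop("each clone needs a positive fraction")
    if (is.null(cl$variants)) clones[[i]]$variants <- character()
    if (is.null(cl$alleles))
      clones[[i]]$alleles <- rep(1L, length(clones[[i]]$variants))
    if (length(clones[[i]]$alleles) != length(clones[[i]]$variants))
      stop("alleles must match variants in length")
  }
  tot <- sum(vapply(clones, `[[`, numeric(1L), "fraction"))
  if (tot > 100 + 1e-9)
    stop("clone fractions sum to ", tot, " > 100")
  structure(list(patient_id = patient_id, clones = clones,
                 het_snps = het_snps, cnloh = cnloh, del17p = del17p,
                 wt_fraction = 100 - tot),
            class = "clonal_architecture")
}

#' Simulate reads over a clonal architecture
#'
#' Reads are drawn per clone proportionally to clone fraction, then from one
#' of the clone's two alleles at random; per-site errors are injected
#' i.i.d. at `error_rate`.  In `tsv` mode the result is a simplified call
#' table (read_id, variant, call); in `sam` mode actual sequences over the
#' reference are written (substitution variants only).  `long_read = TRUE`
#' emulates single-molecule amplicon sequencing: every read spans the whole
#' reference.
#'
#' @param arch A `clonal_architecture` whose variants parse as exonic
#'   substitutions on the reference.
#' @param model A `gene_model`; its CDS is the reference.
#' @param depth Number of reads.
#' @param error_rate Per-site miscall probability.
#' @param read_length Read length for short reads (default 150).
#' @param long_read Span the whole reference (default FALSE).
#' @param seed Integer seed.
#' @param format `"tsv"` (call table) or `"sam"` (alignment file).
#' @param sam_path Output path for `format = "sam"`.
#' @param report_variants Additional variant descriptions to call on every
#'   read (useful for wild-type architectures).
#' @return For `tsv`: list with `calls` (long-format call table) and
#'   `truth` (per-read clone and allele).  For `sam`: the `sam_path`,
#'   invisibly, plus the truth table as an attribute.
#' @export
simulate_reads <- function(arch, model = tp53_model(), depth = 200L,
                           error_rate = 0, read_length = 150L,
                           long_read = FALSE, seed = 1L,
                           format = c("tsv", "sam"), sam_path = NULL,
                           report_variants = NULL) {
  format <- match.arg(format)
  if (depth <= 0L) stop("depth must be positive")
  ref <- model$cds
  L <- nchar(ref)
  vs <- unique(c(report_variants,
                 unlist(lapply(arch$clones, `[[`, "variants"))))
  if (length(vs) == 0L)
    stop("no variants to report; supply report_variants for wild-type runs")
  parsed <- lapply(vs, parse_hgvs_c)
  names(parsed) <- vs
  for (v in parsed) if (!is_exonic(v))
    stop("read simulation supports exonic variants only: ", format_hgvs_c(v))
  pos <- vapply(parsed, `[[`, integer(1L), "start")
  # haplotype pool: (clone, allele) with probability fraction/2 each; the
  # wild-type residual contributes both wild-type alleles
  fr <- vapply(arch$clones, `[[`, numeric(1L), "fraction")
  hap_prob <- c(rep(fr / 2, each = 2L), arch$wt_fraction) / 100
  hap_vars <- c(unlist(lapply(arch$clones, function(cl)
    list(cl$variants[cl$alleles == 1L], cl$variants[cl$alleles == 2L])),
    recursive = FALSE), list(character()))
  local_seed(seed, {
    hap <- sample.int(length(hap_prob), depth, replace = TRUE,
                      prob = hap_prob)
    rl <- if (long_read) L else min(read_length, L)
    starts <- if (long_read) rep(1L, depth)
              else sample.int(L - rl + 1L, depth, replace = TRUE)
    truth <- data.frame(read_id = sprintf("read_%05d", seq_len(depth)),
                        haplotype = hap, start = starts)
    if (format == "tsv") {
      out <- vector("list", depth)
      for (i in seq_len(depth)) {
        carried <- hap_vars[[hap[i]]]
        covered <- pos >= starts[i] & pos <= starts[i] + rl - 1L
        call <- ifelse(!covered, "uncalled",
                       ifelse(vs %in% carried, "alt", "ref"))
        flip <- covered & stats::runif(length(vs)) < error_rate
        call[flip] <- ifelse(call[flip] == "alt", "ref", "alt")
        out[[i]] <- data.frame(read_id = truth$read_id[i], variant = vs,
                               call = call, stringsAsFactors = FALSE)
      }
      list(calls = do.call(rbind, out), truth = truth)
    } else {
      if (is.null(sam_path)) sam_path <- tempfile(fileext = ".sam")
      hap_seqs <- lapply(hap_vars, function(hv) {
        s <- ref
        for (h in hv) {
          v <- parsed[[h]]
          if (v$kind != "substitution")
            stop("SAM simulation supports substitutions only: ", h)
          substr(s, v$start, v$start) <- v$alt
        }
        s
      })
      lines <- c("@HD\tVN:1.6\tSO:unknown",
                 paste0("@SQ\tSN:", model$transcript_id, "_CDS\tLN:", L))
      for (i in seq_len(depth)) {
        sq <- substr(hap_seqs[[hap[i]]], starts[i], starts[i] + rl - 1L)
        err <- which(stats::runif(rl) < error_rate)
        for (e in err) {
          b <- substr(sq, e, e)
          substr(sq, e, e) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }
        lines <- c(lines, paste(truth$read_id[i], 0L,
                                paste0(model$transcript_id, "_CDS"),
                                starts[i], 60L, paste0(rl, "M"), "*", 0L, 0L,
                                sq, strrep("I", rl), sep = "\t"))
      }
      writeLines(lines, sam_path)
      attr(sam_path, "truth") <- truth
      invisible(sam_path)
    }
  })
}

#' Simulate a locus SNP profile
#'
#' Germline-heterozygous SNPs sit at alternate fraction 0.5; a copy-neutral
#' LOH clone at cell fraction g pushes each het SNP to 0.5 +/- g/2 (the sign
#' depending on which haplotype was duplicated, drawn per SNP).  SNPs not in
#' the het set are germline-homozygous (fraction 0 or 1).  Counts are
#' binomially sampled at the given depth.
#'
#' @param arch A `clonal_architecture` (uses `het_snps` and, when `cnloh`,
#'   the first clone's fraction).
#' @param panel SNP panel data frame (`snp_id`, `position`); default the
#'   packaged synthetic panel.
#' @param depth Per-SNP read depth.
#' @param seed Integer seed.
#' @return SNP profile data frame (`snp_id`, `position`, `alt_fraction`,
#'   `depth`).
#' @export
simulate_snp_profile <- function(arch, panel = default_snp_panel(),
                                 depth = 1000L, seed = 1L) {
  if (nrow(panel) == 0L) stop("empty SNP panel")
  g <- if (arch$cnloh && length(arch$clones))
    arch$clones[[1L]]$fraction / 100 else 0
  local_seed(seed, {
    p <- numeric(nrow(panel))
    for (i in seq_len(nrow(panel))) {
      if (panel$snp_id[i] %in% arch$het_snps) {
        dir <- sample(c(-1, 1), 1L)
        p[i] <- 0.5 + dir * g / 2
      } else p[i] <- sample(c(0, 1), 1L)
      # a small uniform base error keeps homozygous fractions off exact 0/1
      p[i] <- min(max(p[i], 0.001), 0.999)
    }
    data.frame(snp_id = panel$snp_id, position = panel$position,
               alt_fraction = stats::rbinom(nrow(panel), depth, p) / depth,
               depth = depth)
  })
}

#' Write a cohort table to TSV
#'
#' @param table Cohort table (as from [simulate_cohort()]).
#' @param path Output path.
#' @export
write_cohort_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
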