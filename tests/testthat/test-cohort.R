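make_cohort <- function(rows) load_cohort(do.call(rbind, rows), TP53)

test_that("load_cohort enforces the schema and reports rejects", {
  expect_error(load_cohort(data.frame(patient_id = "P1", assay = "NGS"),
                           TP53),
               "hgvs_c")
  rows <- rbind(cohort_row("P1", "c.700T>C", vaf = 30),
                cohort_row("P1", "c.700T>C", vaf = 12),   # duplicate
                cohort_row("P1", "c.637C>T", vaf = 8),
                cohort_row("P2", "c.700X>C", vaf = 10),   # parse error
                cohort_row("P3", "c.700T>C", vaf = 120),  # VAF out of range
                cohort_row("P4", "c.700T>C", vaf = 0.5),  # below cutoff
                cohort_row("P5", "c.626_627del", assay = "Sanger"))
  co <- load_cohort(rows, TP53)
  expect_equal(nrow(co$variants), 3L)
  expect_equal(co$n_collapsed, 1L)
  # the duplicate collapse keeps the highest VAF
  expect_equal(co$variants$vaf[co$variants$patient_id == "P1" &
                                 co$variants$hgvs_c == "c.700T>C"], 30)
  expect_equal(nrow(co$rejected), 3L)
  expect_match(co$rejected$reason[co$rejected$row == 4L], "offending token")
  expect_match(co$rejected$reason[co$rejected$row == 5L], "outside")
  expect_match(co$rejected$reason[co$rejected$row == 6L], "cutoff")
  # Sanger rows carry no VAF
  expect_true(is.na(co$variants$vaf[co$variants$assay == "Sanger"]))
})

test_that("a patient assayed twice is counted once, under NGS", {
  co <- load_cohort(rbind(cohort_row("P1", "c.700T>C", vaf = 30),
                          cohort_row("P1", "c.637C>T", assay = "Sanger"),
                          cohort_row("P2", "c.637C>T", assay = "Sanger")),
                    TP53)
  expect_equal(sum(co$patients$patient_id == "P1"), 1L)
  expect_equal(co$patients$assay[co$patients$patient_id == "P1"], "NGS")
  expect_equal(nrow(co$variants), 2L)
})

test_that("class and event spectra are proper distributions", {
  co <- make_cohort(list(cohort_row("P1", "c.700T>C", vaf = 30),
                         cohort_row("P1", "c.637C>T", vaf = 10),
                         cohort_row("P2", "c.626_627del", vaf = 20),
                         cohort_row("P3", "c.673-2A>G", vaf = 5)))
  cs <- class_spectrum(co)
  expect_equal(sum(cs$proportion), 1)
  expect_equal(cs$n[cs$var_class == "missense"], 1L)
  expect_equal(cs$n[cs$var_class == "splice"], 1L)
  es <- event_spectrum(co)
  expect_equal(sum(es$proportion), 1)
  # substitutions only in the denominator: 3 of 4 variants
  expect_equal(sum(es$n), 3L)
  # single-variant cohort sits at 100%
  co1 <- make_cohort(list(cohort_row("P1", "c.700T>C")))
  expect_equal(class_spectrum(co1)$proportion[
    class_spectrum(co1)$var_class == "missense"], 1)
  # an all-CpG C>T cohort is pure GC>AT
  co2 <- make_cohort(list(cohort_row("P1", "c.637C>T"),
                          cohort_row("P2", "c.586C>T")))
  es2 <- event_spectrum(co2)
  expect_equal(es2$proportion[es2$event == "GC>AT"], 1)
  expect_equal(es2$n_cpg[es2$event == "GC>AT"], 2L)
})

test_that("a simulated event mixture is recovered within binomial error", {
  sim <- simulate_cohort(n_patients = 400L, seed = 42L,
                         params = list(n_ngs = 400L))
  co <- load_cohort(sim$table, TP53)
  es <- event_spectrum(co)
  atgc <- es$proportion[es$event == "AT>GC"]
  n_sub <- sum(es$n)
  # target share ~0.20 of substitutions; allow 4 binomial SDs
  tol <- 4 * sqrt(0.2 * 0.8 / n_sub)
  expect_gt(atgc, 0.20 - tol - 0.03)
  expect_lt(atgc, 0.20 + tol + 0.03)
})

test_that("multiclonality labels are a pure function of variant count", {
  rows <- list(cohort_row("S1", "c.700T>C"),
               cohort_row("S2", "c.637C>T"))
  co <- make_cohort(rows)
  mc <- multiclonality(co)
  expect_equal(mc$n_multi, 0L)
  expect_true(all(mc$per_patient$label == "SM"))
  expect_equal(sum(mc$histogram$n), mc$n_patients)

  rows <- list(cohort_row("D1", "c.700T>C", vaf = 10),
               cohort_row("D1", "c.637C>T", vaf = 5),
               cohort_row("T1", "c.700T>C", vaf = 10),
               cohort_row("T1", "c.637C>T", vaf = 5),
               cohort_row("T1", "c.626_627del", vaf = 3),
               cohort_row("Q1", "c.700T>C", vaf = 2),
               cohort_row("Q1", "c.637C>T", vaf = 2),
               cohort_row("Q1", "c.586C>T", vaf = 2),
               cohort_row("Q1", "c.673-2A>G", vaf = 2))
  mc <- multiclonality(make_cohort(rows))
  h <- setNames(mc$histogram$n, mc$histogram$label)
  expect_equal(unname(h[c("SM", "DM", "MM3", "MM4plus")]),
               c(0L, 1L, 1L, 1L))
  expect_equal(mc$range, c(2L, 4L))
})

test_that("cumulated VAF sums exactly and flags only sums above 100", {
  rows <- list(cohort_row("P1", "c.700T>C", vaf = 40),
               cohort_row("P1", "c.637C>T", vaf = 30),
               cohort_row("P1", "c.586C>T", vaf = 20),
               cohort_row("P2", "c.700T>C", vaf = 60),
               cohort_row("P2", "c.626_627del", vaf = 55))
  cv <- cumulated_vaf(make_cohort(rows))
  expect_equal(cv$cum_vaf[cv$patient_id == "P1"], 90)
  expect_false(cv$exceeds_100[cv$patient_id == "P1"])
  expect_equal(cv$cum_vaf[cv$patient_id == "P2"], 115)
  expect_true(cv$exceeds_100[cv$patient_id == "P2"])
})

test_that("low-VAF census counts match direct enumeration", {
  sim <- simulate_cohort(n_patients = 150L, seed = 9L,
                         params = list(n_ngs = 150L))
  co <- load_cohort(sim$table, TP53)
  cen <- low_vaf_census(co, 1, 5)
  v <- co$variants
  in_band <- v$vaf >= 1 & v$vaf <= 5
  expect_equal(cen$n_variants, sum(in_band))
  expect_equal(cen$n_patients, length(unique(v$patient_id[in_band])))
  expect_equal(cen$n_patients_single + cen$n_patients_multi, cen$n_patients)
  expect_error(low_vaf_census(co, 5, 1), "lo")
  empty <- low_vaf_census(co, 0.01, 0.02)
  expect_equal(empty$n_patients, 0L)
})

test_that("hotspot enrichment equals the closed-form chi-square", {
  res <- hotspot_enrichment(17, 100, 2, 100, method = "chi2")
  expect_equal(res$statistic, chi2_oracle(17, 83, 2, 98), tolerance = 1e-12)
  # exhaustive small tables
  for (a in seq(0, 12, 3)) for (c_ in seq(0, 12, 3))
    for (ta in c(12, 20)) for (tb in c(12, 30)) {
      if (a > ta || c_ > tb || (a == 0 && c_ == 0) ||
          (a == ta && c_ == tb)) next
      res <- hotspot_enrichment(a, ta, c_, tb, method = "chi2")
      expect_equal(res$statistic, chi2_oracle(a, ta - a, c_, tb - c_),
                   tolerance = 1e-12)
    }
  # identical proportions: no association
  res <- hotspot_enrichment(10, 100, 10, 100, method = "chi2")
  expect_equal(res$p_value, 1)
  expect_equal(res$odds_ratio, 1)
  # sparse tables fall back to Fisher; zero cells get the Haldane OR
  res <- hotspot_enrichment(2, 100, 0, 100)
  expect_equal(res$method, "fisher")
  expect_true(is.finite(res$odds_ratio))
  expect_error(hotspot_enrichment(5, 0, 1, 10), "zero total")
  expect_error(hotspot_enrichment(5, 4, 1, 10), "focal")
})

test_that("frameshift codon distribution uses normalized first-base codons", {
  rows <- list(cohort_row("P1", "c.626_627del", vaf = 10),
               cohort_row("P2", "c.626_627del", vaf = 5),
               cohort_row("P3", "c.629del", vaf = 5))
  fd <- frameshift_codon_distribution(make_cohort(rows))
  expect_equal(sum(fd$proportion), 1)
  expect_equal(fd$codon[1L], 209L)
  expect_equal(fd$proportion[1L], 2 / 3)
  expect_equal(fd$codon[fd$hgvs_c == "c.629del"], 210L)
  # single-frameshift cohort is 100% at its codon
  fd1 <- frameshift_codon_distribution(
    make_cohort(list(cohort_row("P1", "c.626_627del"))))
  expect_equal(fd1$proportion, 1)
})

test_that("splice distribution pools a signal's two positions", {
  rows <- list(cohort_row("P1", "c.673-2A>G", vaf = 4),
               cohort_row("P2", "c.673-2A>T", vaf = 4),
               cohort_row("P3", "c.673-1G>A", vaf = 4),
               cohort_row("P4", "c.672+1G>A", vaf = 4))
  sd_ <- splice_signal_distribution(make_cohort(rows), TP53)
  bys <- sd_$by_signal
  expect_equal(sum(bys$proportion), 1)
  expect_equal(bys$proportion[bys$label == "intron6_acceptor"], 3 / 4)
  expect_equal(bys$proportion[bys$label == "intron6_donor"], 1 / 4)
  byp <- sd_$by_position
  expect_equal(byp$n[byp$position == "673-2"], 2L)
  # toy cohort with one donor signal only
  sd1 <- splice_signal_distribution(
    make_cohort(list(cohort_row("P1", "c.672+1G>T"))), TP53)
  expect_equal(sd1$by_signal$proportion[
    sd1$by_signal$label == "intron6_donor"], 1)
})

test_that("uniform simulated draws give flat distributions", {
  set.seed(5)
  # frameshifts drawn uniformly over 40 1-nt deletion sites; the expected
  # per-codon mass follows the (normalization-aware) site-to-codon map
  starts <- as.integer(round(seq(4L, 1100L, length.out = 40L)))
  codon_of <- vapply(starts, function(p)
    classify_variant(paste0("c.", p, "del"), TP53)$codon, integer(1L))
  rows <- lapply(seq_len(800L), function(i)
    cohort_row(paste0("U", i), paste0("c.", sample(starts, 1L), "del"),
               vaf = 10))
  fd <- frameshift_codon_distribution(make_cohort(rows))
  expected <- table(codon_of)[as.character(fd$codon)] / length(starts)
  gof <- suppressWarnings(
    stats::chisq.test(fd$n, p = as.numeric(expected), rescale.p = TRUE))
  expect_gt(gof$p.value, 0.001)
  # splice variants drawn uniformly over the 20 signals stay near 5% each
  cat_ <- splice_signal_catalogue(TP53)
  ref_of <- function(side, off) if (side == "donor") c("G", "T")[off]
            else c("A", "G")[off + 3L]
  srows <- lapply(seq_len(1000L), function(i) {
    r <- cat_[sample.int(20L, 1L), ]
    off <- sample(if (r$side == "donor") 1:2 else -(2:1), 1L)
    ref <- ref_of(r$side, off)
    cohort_row(paste0("S", i),
               paste0("c.", format_cpos(r$anchor, off), ref, ">",
                      setdiff(c("A", "C"), ref)[1L]), vaf = 10)
  })
  sd_ <- splice_signal_distribution(make_cohort(srows), TP53)
  expect_true(all(abs(sd_$by_signal$proportion - 0.05) < 0.035))
})

test_that("VAF group comparison behaves under identity and the null", {
  # identical groups: pure ties, p = 1
  rows <- c(lapply(1:8, function(i)
              cohort_row(paste0("A", i), "c.700T>C", vaf = 10,
                         pathogenicity = "P")),
            lapply(1:8, function(i)
              cohort_row(paste0("B", i), "c.637C>T", vaf = 10,
                         pathogenicity = "VUS")))
  res <- vaf_group_comparison(make_cohort(rows))
  expect_equal(res$p_value, 1)
  # null simulation: groups drawn from one distribution rarely reject
  set.seed(12)
  pvals <- replicate(60, {
    rows <- lapply(1:40, function(i)
      cohort_row(paste0("P", i), "c.700T>C",
                 vaf = round(stats::rlnorm(1, 2.5, 0.8) + 1, 1),
                 pathogenicity = sample(c("P", "LP", "VUS"), 1L)))
    res <- vaf_group_comparison(load_cohort(do.call(rbind, rows), TP53))
    min(res$p_value)
  })
  expect_gt(mean(pvals > 0.05), 0.75)
  # small groups are skipped with notice
  rows <- c(lapply(1:5, function(i)
    cohort_row(paste0("P", i), "c.700T>C", vaf = i * 5,
               pathogenicity = c("P", "P", "P", "LP", "LP")[i])),
    list(cohort_row("Q1", "c.637C>T", vaf = 12, pathogenicity = "VUS")))
  res <- vaf_group_comparison(make_cohort(rows), min_n = 2L)
  expect_equal(attr(res, "skipped"), "VUS")
})
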