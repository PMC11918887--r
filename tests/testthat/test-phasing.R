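test_that("pair eligibility requires same exon within the distance bound", {
  # two codon-234 substitutions sit 1 nt apart in exon 7
  expect_true(pair_eligibility("c.700T>C", "c.701A>G", TP53))
  # different exons
  expect_false(pair_eligibility("c.700T>C", "c.637C>T", TP53))
  # same exon (8), distance exactly 50: inclusive bound
  expect_true(pair_eligibility("c.818G>A", "c.868C>T", TP53))
  expect_false(pair_eligibility("c.818G>A", "c.869A>T", TP53))
  # intronic variants are never eligible
  expect_false(pair_eligibility("c.673-2A>G", "c.700T>C", TP53))
})

counts_to_calls <- function(n_rr, n_ar, n_ra, n_aa) {
  mk <- function(c1, c2, n, off) {
    if (n == 0L) return(NULL)
    ids <- sprintf("r%04d", off + seq_len(n))
    rbind(data.frame(read_id = ids, variant = "v1", call = c1),
          data.frame(read_id = ids, variant = "v2", call = c2))
  }
  do.call(rbind, list(mk("ref", "ref", n_rr, 0L),
                      mk("alt", "ref", n_ar, n_rr),
                      mk("ref", "alt", n_ra, n_rr + n_ar),
                      mk("alt", "alt", n_aa, n_rr + n_ar + n_ra)))
}

test_that("phase_pair decides cis, trans and ambiguous as specified", {
  # 45 ref/ref, 30 alt1, 25 alt2, 0 alt/alt -> trans
  pc <- phase_pair(counts_to_calls(45L, 30L, 25L, 0L), "v1", "v2")
  expect_equal(pc$configuration, "trans")
  expect_equal(unname(pc$counts),
               c(45L, 30L, 25L, 0L))
  # 60 ref/ref, 0 single-alt, 40 alt/alt -> cis
  pc <- phase_pair(counts_to_calls(60L, 0L, 0L, 40L), "v1", "v2")
  expect_equal(pc$configuration, "cis")
  # too few doubly-called reads -> ambiguous with reason
  pc <- phase_pair(counts_to_calls(5L, 3L, 2L, 0L), "v1", "v2")
  expect_equal(pc$configuration, "ambiguous")
  expect_match(pc$reason, "insufficient")
  # mixed signal -> ambiguous, never both cis and trans
  pc <- phase_pair(counts_to_calls(40L, 25L, 25L, 25L), "v1", "v2")
  expect_equal(pc$configuration, "ambiguous")
})

test_that("error-free reads recover the simulated configuration", {
  pair <- c("c.700T>C", "c.713G>A")
  for (config in c("cis", "trans")) for (depth in seq(80L, 200L, 60L)) {
    arch <- if (config == "cis")
      clonal_architecture(list(list(fraction = 60, variants = pair,
                                    alleles = c(1L, 1L))))
    else
      clonal_architecture(list(list(fraction = 50, variants = pair[1L],
                                    alleles = 1L),
                               list(fraction = 50, variants = pair[2L],
                                    alleles = 1L)))
    sim <- simulate_reads(arch, TP53, depth = depth, error_rate = 0,
                          long_read = TRUE, seed = depth)
    pc <- phase_pair(sim$calls, pair[1L], pair[2L], min_support = 10L)
    expect_equal(pc$configuration, config)
    # error-free construction: no impossible haplotypes
    if (config == "trans") expect_equal(unname(pc$counts["n_alt_alt"]), 0L)
    if (config == "cis") {
      expect_equal(unname(pc$counts["n_alt_ref"]), 0L)
      expect_equal(unname(pc$counts["n_ref_alt"]), 0L)
    }
  }
})

test_that("at 0.5% per-site error the error bound absorbs stray calls", {
  pair <- c("c.700T>C", "c.713G>A")
  arch <- clonal_architecture(list(list(fraction = 45, variants = pair[1L]),
                                   list(fraction = 45, variants = pair[2L])))
  sim <- simulate_reads(arch, TP53, depth = 1000L, error_rate = 0.005,
                        long_read = TRUE, seed = 77L)
  pc <- phase_pair(sim$calls, pair[1L], pair[2L], error_rate = 0.005)
  expect_equal(pc$configuration, "trans")
  # closed-form check: double-alt count within the binomial 0.999 bound
  expect_lte(unname(pc$counts["n_alt_alt"]),
             stats::qbinom(0.999, pc$n_double_called, 0.005))
})

test_that("short reads only call covered positions", {
  pair <- c("c.700T>C", "c.713G>A")
  arch <- clonal_architecture(list(list(fraction = 50, variants = pair,
                                        alleles = c(1L, 1L))))
  sim <- simulate_reads(arch, TP53, depth = 300L, error_rate = 0,
                        read_length = 100L, seed = 3L)
  calls <- sim$calls
  expect_true(any(calls$call == "uncalled"))
  pc <- phase_pair(calls, pair[1L], pair[2L], min_support = 10L)
  expect_equal(pc$configuration, "cis")
})

test_that("allele reconstruction recovers clone fractions from long reads", {
  arch <- clonal_architecture(list(
    list(fraction = 30, variants = "c.700T>C"),
    list(fraction = 20, variants = "c.742C>T")))
  sim <- simulate_reads(arch, TP53, depth = 500L, error_rate = 0.005,
                        long_read = TRUE, seed = 21L)
  at <- reconstruct_alleles(sim$calls, c("c.700T>C", "c.742C>T"))
  expect_equal(sum(at$frequency), 1)
  f <- setNames(at$frequency, at$signature)
  # reads sample haplotypes: a clone at fraction f carries its variant on
  # one of two alleles, so expected allele frequency is f/2
  expect_lt(abs(f[["wt"]] - 0.75), 0.05)
  expect_lt(abs(f[["c.700T>C"]] - 0.15), 0.05)
  expect_lt(abs(f[["c.742C>T"]] - 0.10), 0.05)
  # single wild-type clone: one signature at frequency 1
  wt <- clonal_architecture(list(list(fraction = 100,
                                      variants = character())))
  simw <- simulate_reads(wt, TP53, depth = 50L, error_rate = 0,
                         long_read = TRUE, seed = 4L,
                         report_variants = "c.700T>C")
  atw <- reconstruct_alleles(simw$calls, "c.700T>C")
  expect_equal(atw$signature, "wt")
  expect_equal(atw$frequency, 1)
  # a cis clone yields one combined signature
  cis <- clonal_architecture(list(list(fraction = 80,
                                       variants = c("c.700T>C", "c.713G>A"),
                                       alleles = c(1L, 1L))))
  simc <- simulate_reads(cis, TP53, depth = 400L, error_rate = 0,
                         long_read = TRUE, seed = 5L)
  atc <- reconstruct_alleles(simc$calls, c("c.700T>C", "c.713G>A"))
  fc <- setNames(atc$frequency, atc$signature)
  expect_lt(abs(fc[["c.700T>C+c.713G>A"]] - 0.4), 0.07)
  expect_false("c.700T>C" %in% atc$signature)   # no single-alt allele in cis
})

test_that("reconstruction frequencies converge with read depth", {
  arch <- clonal_architecture(list(list(fraction = 50,
                                        variants = "c.700T>C")))
  err <- vapply(c(100L, 1000L), function(d) {
    sim <- simulate_reads(arch, TP53, depth = d, error_rate = 0,
                          long_read = TRUE, seed = d + 1L)
    at <- reconstruct_alleles(sim$calls, "c.700T>C")
    abs(at$frequency[at$signature == "c.700T>C"] - 0.25)
  }, numeric(1L))
  expect_lt(err[1L], 0.15)
  expect_lt(err[2L], 0.05)
})

test_that("SAM-derived calls match the simulator's truth", {
  pair <- c("c.700T>C", "c.713G>A")
  arch <- clonal_architecture(list(list(fraction = 40, variants = pair[1L]),
                                   list(fraction = 40,
                                        variants = pair[2L])))
  sam <- withr::local_tempfile(fileext = ".sam")
  simulate_reads(arch, TP53, depth = 150L, error_rate = 0,
                 long_read = TRUE, seed = 13L, format = "sam",
                 sam_path = sam)
  vars <- data.frame(variant = pair, pos = c(700L, 713L),
                     ref = c("T", "G"), alt = c("C", "A"))
  calls <- sam_allele_calls(sam, vars)
  pc <- phase_pair(calls, pair[1L], pair[2L])
  expect_equal(pc$configuration, "trans")
  # the same seed through the TSV path gives identical haplotype counts
  sim <- simulate_reads(arch, TP53, depth = 150L, error_rate = 0,
                        long_read = TRUE, seed = 13L)
  pc2 <- phase_pair(sim$calls, pair[1L], pair[2L])
  expect_equal(pc$counts, pc2$counts)
})

test_that("soft-clipped and deleted positions are uncalled", {
  sam <- withr::local_tempfile(fileext = ".sam")
  ref <- TP53$cds
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:NM_000546_CDS\tLN:", nchar(ref)),
             paste("r1", 0, "NM_000546_CDS", 691, 60, "20M",
                   "*", 0, 0, substr(ref, 691, 710), strrep("I", 20),
                   sep = "\t"),
             # 5S: first five bases clipped, alignment starts at 705
             paste("r2", 0, "NM_000546_CDS", 705, 60, "5S15M",
                   "*", 0, 0, substr(ref, 700, 719), strrep("I", 20),
                   sep = "\t"),
             # 10-nt deletion spanning position 700
             paste("r3", 0, "NM_000546_CDS", 691, 60, "5M10D15M",
                   "*", 0, 0, paste0(substr(ref, 691, 695),
                                     substr(ref, 706, 720)),
                   strrep("I", 20), sep = "\t"))
  writeLines(lines, sam)
  calls <- sam_allele_calls(sam, data.frame(variant = "v", pos = 700L,
                                            ref = "T", alt = "C"))
  got <- setNames(calls$call, calls$read_id)
  expect_equal(unname(got["r1"]), "ref")
  expect_equal(unname(got["r2"]), "uncalled")
  expect_equal(unname(got["r3"]), "uncalled")
})
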