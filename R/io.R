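# Run configuration and machine-readable summaries.  The package's
# workflow surface is the set of analysis scripts shipped under analysis/;
# these helpers give them a common, round-trippable configuration and a
# JSON summary writer.

#' Build a validated run configuration
#'
#' @param reference,cohort_table,reads,snp_panel Input paths (optional).
#' @param output_dir Output directory.
#' @param seed Integer seed.
#' @param vaf_cutoff NGS reporting cutoff in percent (0-100).
#' @param min_support Phasing haplotype support (>= 1 read).
#' @param error_rate Per-site miscall rate (0-1).
#' @param het_band Heterozygous band on the SNP alternate fraction.
#' @param min_depth Minimum informative SNP depth.
#' @return A `run_config` list.
#' @export
run_config <- function(reference = NULL, cohort_table = NULL, reads = NULL,
                       snp_panel = NULL, output_dir = ".", seed = 1L,
                       vaf_cutoff = 1, min_support = 20L,
                       error_rate = 0.005, het_band = c(0.10, 0.90),
                       min_depth = 100L) {
  if (vaf_cutoff < 0 || vaf_cutoff > 100) stop("vaf_cutoff outside [0,100]")
  if (min_support < 1L) stop("min_support must be >= 1")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate outside [0,1)")
  if (length(het_band) != 2L || het_band[1L] >= het_band[2L] ||
      het_band[1L] < 0 || het_band[2L] > 1)
    stop("het_band must be an increasing pair inside [0,1]")
  if (min_depth < 1L) stop("min_depth must be >= 1")
  structure(list(reference = reference, cohort_table = cohort_table,
                 reads = reads, snp_panel = snp_panel,
                 output_dir = output_dir, seed = as.integer(seed),
                 vaf_cutoff = vaf_cutoff,
                 min_support = as.integer(min_support),
                 error_rate = error_rate, het_band = het_band,
                 min_depth = as.integer(min_depth)),
            class = "run_config")
}

#' Write / read a run configuration (lossless JSON round trip)
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1L))])
}

#' Write a named list of numbers as a JSON summary
#' @param x Named list.
#' @param path File path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
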