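#' Filter-cascade parameters
#'
#' Thresholds of the five-step post-calling SNP filter cascade, in cascade
#' order: (1) remove SNPs with zero read coverage in at least
#' `max_zero_coverage_pops` populations; (2) remove SNPs whose mean
#' relative coverage across populations exceeds `max_mean_rel_cov`
#' (collapsed multi-copy regions); (3) remove SNPs whose standard deviation
#' of allele frequency across covered populations is below `min_sd_freq`
#' (near-invariant artifacts); (4) remove SNPs whose mean relative coverage
#' is below `min_mean_rel_cov` (presence/absence regions); (5) remove SNPs
#' monomorphic in more than `max_monomorphic_fraction` of the populations
#' (rare-allele bias).
#'
#' `max_zero_coverage_pops` is interpreted as a count out of
#' `reference_n_pops` populations and rescaled proportionally when the
#' dataset has a different number of populations.
#'
#' @param max_zero_coverage_pops Count of zero-coverage populations at
#'   which a SNP is dropped (default 8 of 168).
#' @param max_mean_rel_cov,min_mean_rel_cov Bounds on mean relative
#'   coverage.
#' @param min_sd_freq Minimum allele-frequency standard deviation.
#' @param max_monomorphic_fraction Strict upper bound on the fraction of
#'   monomorphic populations.
#' @param reference_n_pops Population count the zero-coverage threshold
#'   refers to.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(max_zero_coverage_pops = 8,
                          max_mean_rel_cov = 1.5,
                          min_sd_freq = 0.004,
                          min_mean_rel_cov = 0.5,
                          max_monomorphic_fraction = 0.90,
                          reference_n_pops = 168) {
  stopifnot(min_mean_rel_cov < max_mean_rel_cov)
  structure(list(
    max_zero_coverage_pops = max_zero_coverage_pops,
    max_mean_rel_cov = max_mean_rel_cov,
    min_sd_freq = min_sd_freq,
    min_mean_rel_cov = min_mean_rel_cov,
    max_monomorphic_fraction = max_monomorphic_fraction,
    reference_n_pops = reference_n_pops
  ), class = "filter_params")
}

#' Relative coverage per SNP and population
#'
#' A SNP's coverage divided by the median coverage of its population
#' (median over all SNPs in that population); values well above 1 flag
#' collapsed paralogs, values well below 1 flag presence/absence variation.
#'
#' @param x A [pool_counts] object.
#' @return Numeric matrix, SNP x population.
#' @export
relative_coverage <- function(x) {
  cov <- coverage(x)
  med <- apply(cov, 2, median)
  if (any(med == 0)) {
    abort(paste0("population with median coverage 0: ",
                 x$pop_ids[which(med == 0)[1]]))
  }
  sweep(cov, 2, med, "/")
}

#' Apply the five-step SNP filter cascade
#'
#' Filters are applied strictly in order; a SNP is removed at the first
#' step it fails, so each step's removal count refers to the SNPs still
#' present when it runs. Frequency statistics use populations with
#' non-zero coverage only; relative coverage is computed once on the input
#' matrix.
#'
#' @param x A [pool_counts] object.
#' @param params A [filter_params()].
#' @return A list with `counts` (the filtered [pool_counts]) and `report`,
#'   a tibble with one row per step: `step`, `n_removed`, `n_remaining`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_pops = 8, n_snps = 200, n_assoc = 0),
#'                         seed = 1)
#' apply_filter_cascade(sim$counts, filter_params())$report
#' @export
apply_filter_cascade <- function(x, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  n0 <- nrow(x$snps)
  if (n0 == 0) abort("empty input matrix")
  J <- length(x$pop_ids)
  cov <- coverage(x)
  relcov <- relative_coverage(x)
  f <- allele_freq(x)

  zero_thr <- params$max_zero_coverage_pops * J / params$reference_n_pops
  keep <- rep(TRUE, n0)
  report <- list()
  note <- function(name, fail) {
    drop <- keep & fail
    keep <<- keep & !fail
    report[[length(report) + 1]] <<- tibble(
      step = name, n_removed = sum(drop), n_remaining = sum(keep))
  }

  note("zero_coverage_pops", rowSums(cov == 0) >= zero_thr)
  note("high_mean_rel_cov", rowMeans(relcov) > params$max_mean_rel_cov)
  sd_f <- apply(f, 1, sd, na.rm = TRUE)
  sd_f[is.na(sd_f)] <- 0
  note("low_sd_freq", sd_f < params$min_sd_freq)
  note("low_mean_rel_cov", rowMeans(relcov) < params$min_mean_rel_cov)
  n_cov <- rowSums(cov > 0)
  n_mono <- rowSums(f == 0 | f == 1, na.rm = TRUE)
  note("monomorphic", n_mono > params$max_monomorphic_fraction * pmax(n_cov, 1))

  list(counts = slice_snps(x, keep), report = dplyr::bind_rows(report))
}
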