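#' Standardize a covariate
#'
#' Centers to mean 0 and scales to standard deviation 1 (n - 1
#' denominator). Idempotent on already-standardized input.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Standardized numeric vector.
#' @export
standardize_covariate <- function(values) {
  if (length(unique(values)) < 2) abort("constant covariate: standardization undefined")
  as.numeric(scale(values))
}

is_standardized <- function(z, tol = 1e-6) {
  abs(mean(z)) < tol && abs(sd(z) - 1) < tol
}

#' Genome-environment association scan under the AUX model
#'
#' Extends the core hierarchical model with a per-SNP spike-and-slab
#' regression of population allele frequencies on a standardized
#' covariate: a binary auxiliary indicator `delta_i` switches the SNP's
#' regression coefficient `beta_i` (uniform prior on
#' `(-beta_bound, beta_bound)`) on or off, and the shared inclusion
#' probability P gets a conjugate Beta(1, 1) update, which makes the scan
#' self-correcting for multiple testing. Omega is held fixed at the
#' supplied estimate. Per SNP the scan reports the posterior inclusion
#' probability (PIP, posterior mean of `delta_i`), the effect estimate
#' `beta_hat` (posterior mean of `delta_i * beta_i`), and the Bayes
#' factor in deciban, `10 * log10` of the ratio of posterior odds
#' (from the PIP) to prior odds (from the posterior mean of P). The PIP
#' is clamped to `[1/(2S), 1 - 1/(2S)]` with S retained samples so the BF
#' stays finite; the cap is recorded in the result.
#'
#' @param x A [pool_counts] object.
#' @param omega Fixed Omega (matrix or `omega_fit`), normally the core
#'   model's posterior mean.
#' @param covariate Standardized covariate, one value per population.
#' @param pops,pool_sizes Haploid pool sizes (see [estimate_core_model()]).
#' @param settings An [mcmc_settings()].
#' @param seed RNG seed.
#' @param beta_bound Half-width of the uniform prior on beta (default
#'   0.3).
#' @param xtx Optional per-SNP XtX values to join into the result.
#' @return An object of class `aux_scan`; `tidy()` returns the per-SNP
#'   tibble with columns `chrom`, `pos`, `snp_id`, `pip`, `beta`,
#'   `bf_db`, `xtx`.
#' @export
run_aux_scan <- function(x, omega, covariate, pops = NULL, pool_sizes = NULL,
                         settings = mcmc_settings(), seed = NULL,
                         beta_bound = 0.3, xtx = NULL) {
  J <- length(x$pop_ids)
  if (length(covariate) != J) abort("covariate length must match populations")
  if (!is_standardized(covariate)) abort("covariate must be standardized (see standardize_covariate)")
  om <- as_omega_matrix(omega)
  if (nrow(om) != J) abort("omega dimension does not match populations")
  ps <- resolve_pool_sizes(x, pops, pool_sizes)
  if (!is.null(seed)) set.seed(seed)
  raw <- .gea_mcmc(x$ref, coverage(x), ps, om,
                   FALSE, TRUE, as.numeric(covariate), beta_bound,
                   1, 1,
                   settings$n_pilot, settings$pilot_length, settings$burn_in,
                   settings$n_samples, settings$thin, FALSE)
  S <- raw$n_samples
  cap <- 1 / (2 * S)
  pip <- pmin(pmax(as.numeric(raw$pip), cap), 1 - cap)
  p_mean <- min(max(raw$p_mean, cap), 1 - cap)
  bf <- (pip / (1 - pip)) / (p_mean / (1 - p_mean))
  res <- dplyr::bind_cols(
    x$snps,
    tibble(pip = pip, beta = as.numeric(raw$beta_hat),
           bf_db = 10 * log10(bf),
           xtx = if (is.null(xtx)) NA_real_ else as.numeric(xtx)))
  structure(list(
    results = res, p_mean = raw$p_mean, covariate = covariate,
    beta_bound = beta_bound, settings = settings, seed = seed,
    n_samples = S, pip_cap = cap, subset_id = NA_integer_,
    acceptance = c(alpha = raw$acc_alpha, pi = raw$acc_pi)
  ), class = "aux_scan")
}

#' @export
print.aux_scan <- function(x, ...) {
  cat("<aux_scan> ", nrow(x$results), " SNPs; posterior mean P = ",
      signif(x$p_mean, 3), "; max |BF| ",
      signif(max(abs(x$results$bf_db)), 3), " dB\n", sep = "")
  invisible(x)
}

#' @export
tidy.aux_scan <- function(x, ...) x$results

#' @export
glance.aux_scan <- function(x, ...) {
  tibble(n_snps = nrow(x$results), p_mean = x$p_mean,
         n_samples = x$n_samples,
         max_bf_db = max(x$results$bf_db),
         n_bf20 = sum(x$results$bf_db > 20))
}

#' Merge per-subset scan results
#'
#' Concatenates AUX scans run in parallel on disjoint interleaved SNP
#' subsets (same covariate, same Omega) back into genome order,
#' retaining subset provenance.
#'
#' @param scans A list of `aux_scan` objects.
#' @return An `aux_scan` covering the union of SNPs.
#' @export
merge_scan_outputs <- function(scans) {
  stopifnot(length(scans) >= 1)
  if (length(scans) == 1) return(scans[[1]])
  tabs <- purrr::imap(scans, function(s, k) dplyr::mutate(tidy(s), subset = k))
  all <- dplyr::bind_rows(tabs)
  if (anyDuplicated(all$snp_id)) abort("overlapping SNP ids across subsets")
  out <- scans[[1]]
  out$results <- dplyr::arrange(all, match(.data$chrom, unique(.data$chrom)), .data$pos)
  out$p_mean <- mean(purrr::map_dbl(scans, "p_mean"))
  out
}

#' Manhattan plot of an association scan
#'
#' @param object An `aux_scan`.
#' @param y Column to plot (`"bf_db"`, `"beta"`, `"pip"` or `"xtx"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aux_scan <- function(object, y = "bf_db", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data[[y]],
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = y) +
    ggplot2::theme_minimal()
}
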