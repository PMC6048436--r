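#' MCMC settings
#'
#' Sampler schedule for the hierarchical model. The defaults mirror the
#' settings used for the full-genome analysis (15 pilot runs of 500
#' iterations tuning proposal widths to a 25-45% acceptance window, then a
#' burn-in of 2,500 iterations and 1,000 retained samples thinned by 20).
#' Desk-scale analyses and simulations can use much shorter schedules; see
#' the methods vignette.
#'
#' @param n_pilot,pilot_length Pilot runs used for proposal-width tuning.
#' @param burn_in Burn-in iterations after tuning.
#' @param n_samples Retained posterior samples.
#' @param thin Thinning interval between retained samples.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_pilot = 15, pilot_length = 500, burn_in = 2500,
                          n_samples = 1000, thin = 20) {
  stopifnot(n_pilot >= 0, burn_in >= 0, n_samples >= 1, thin >= 1)
  structure(list(n_pilot = n_pilot, pilot_length = pilot_length,
                 burn_in = burn_in, n_samples = n_samples, thin = thin),
            class = "mcmc_settings")
}

#' Short MCMC schedule for desk-scale datasets
#' @rdname mcmc_settings
#' @export
mcmc_settings_desk <- function() {
  mcmc_settings(n_pilot = 4, pilot_length = 100, burn_in = 400,
                n_samples = 400, thin = 2)
}

#' Estimate the core hierarchical model
#'
#' Fits the covariance model of population allele frequencies to Pool-Seq
#' read counts by Metropolis-within-Gibbs sampling: latent pool allele
#' counts are updated by +/-1 random-walk proposals, population
#' frequencies by reflected Gaussian random walks on [0, 1], the
#' across-population frequency of each SNP by a reflected random walk
#' under a Beta prior, and the scaled covariance matrix Omega by a
#' conjugate inverse-Wishart step (identity prior scale, J + 2 degrees of
#' freedom) on the standardized residuals. Returns the posterior-mean
#' Omega with its eigen-decomposition and per-SNP posterior summaries
#' including the XtX differentiation statistic.
#'
#' @param x A [pool_counts] object (normally post-filtering).
#' @param pops A [population_set] matching `x` (haploid pool sizes).
#' @param settings An [mcmc_settings()].
#' @param seed RNG seed for a reproducible chain.
#' @param pi_prior Length-2 Beta shape parameters of the across-population
#'   frequency prior (fixed, not sampled).
#' @param omega_init Initial Omega (default identity).
#' @param keep_cross Keep per-SNP posterior second-moment matrices of the
#'   standardized frequencies (needed by [compute_xtx()]; memory is
#'   n_snps x J x J doubles).
#' @return An object of class `core_model_fit`: `omega` (an `omega_fit`),
#'   per-SNP tibble via [tidy()], acceptance rates and settings.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(n_pops = 6, n_snps = 300, n_assoc = 0,
#'                                    omega_spec = omega_identity(6)), seed = 1)
#' fit <- estimate_core_model(sim$counts, pool_sizes = 30,
#'                            settings = mcmc_settings_desk(), seed = 1)
#' glance(fit)
#' }
#' @param pool_sizes Alternative to `pops`: haploid pool sizes recycled
#'   over populations.
#' @export
estimate_core_model <- function(x, pops = NULL, pool_sizes = NULL,
                                settings = mcmc_settings(), seed = NULL,
                                pi_prior = c(2.78, 0.710), omega_init = NULL,
                                keep_cross = TRUE) {
  J <- length(x$pop_ids)
  if (J < 3) abort("at least 3 populations are required")
  ps <- resolve_pool_sizes(x, pops, pool_sizes)
  if (is.null(omega_init)) omega_init <- diag(J)
  if (!is.null(seed)) set.seed(seed)
  raw <- .gea_mcmc(x$ref, coverage(x), ps, omega_init,
                   TRUE, FALSE, numeric(J), 0.3,
                   pi_prior[1], pi_prior[2],
                   settings$n_pilot, settings$pilot_length, settings$burn_in,
                   settings$n_samples, settings$thin, keep_cross)
  omega <- omega_fit(raw$omega, pop_ids = x$pop_ids)
  structure(list(
    omega = omega,
    snps = x$snps,
    pi = as.numeric(raw$pi),
    xtx = as.numeric(raw$xtx),
    alpha = raw$alpha,
    cross = if (keep_cross) raw$cross else NULL,
    n_samples = raw$n_samples,
    acceptance = c(alpha = raw$acc_alpha, pi = raw$acc_pi),
    settings = settings, seed = seed, pop_ids = x$pop_ids
  ), class = "core_model_fit")
}

resolve_pool_sizes <- function(x, pops, pool_sizes) {
  J <- length(x$pop_ids)
  if (!is.null(pops)) {
    if (!all(x$pop_ids %in% pops$pop_id)) abort("populations missing from `pops`")
    as.integer(pops$haploid_pool_size[match(x$pop_ids, pops$pop_id)])
  } else if (!is.null(pool_sizes)) {
    as.integer(rep_len(pool_sizes, J))
  } else {
    abort("provide `pops` or `pool_sizes`")
  }
}

#' @export
print.core_model_fit <- function(x, ...) {
  cat("<core_model_fit> ", length(x$xtx), " SNPs x ", length(x$pop_ids),
      " populations; ", x$n_samples, " posterior samples\n", sep = "")
  invisible(x)
}

#' @export
tidy.core_model_fit <- function(x, ...) {
  dplyr::bind_cols(x$snps, tibble(pi = x$pi, xtx = x$xtx))
}

#' @export
glance.core_model_fit <- function(x, ...) {
  tibble(n_snps = length(x$xtx), n_pops = length(x$pop_ids),
         n_samples = x$n_samples,
         acc_alpha = x$acceptance[["alpha"]], acc_pi = x$acceptance[["pi"]],
         mean_xtx = mean(x$xtx))
}

#' Scaled covariance matrix container
#'
#' Wraps a symmetric positive-definite Omega estimate with its
#' eigen-decomposition (the genomic principal components).
#'
#' @param omega J x J matrix.
#' @param pop_ids Optional population identifiers.
#' @param source_subset_id Optional provenance label.
#' @return An object of class `omega_fit`.
#' @export
omega_fit <- function(omega, pop_ids = NULL, source_subset_id = NULL) {
  omega <- check_pos_def(omega)
  ev <- eigen(omega, symmetric = TRUE)
  structure(list(omega = omega, eigenvalues = ev$values,
                 eigenvectors = ev$vectors,
                 pop_ids = pop_ids, source_subset_id = source_subset_id),
            class = "omega_fit")
}

#' @export
print.omega_fit <- function(x, ...) {
  cat("<omega_fit> ", nrow(x$omega), " populations; PC1 fraction ",
      round(100 * x$eigenvalues[1] / sum(x$eigenvalues), 1), "%\n", sep = "")
  invisible(x)
}

as_omega_matrix <- function(x) {
  if (inherits(x, "omega_fit")) x$omega
  else if (inherits(x, "core_model_fit")) x$omega$omega
  else check_pos_def(as.matrix(x))
}

#' Forstner-Moonen distance between covariance matrices
#'
#' `sqrt(sum(log(lambda_k)^2))` over the generalized eigenvalues
#' `lambda_k` of the pair (a, b); a proper metric on the positive-definite
#' cone: symmetric, zero iff the matrices are equal.
#'
#' @param a,b Positive-definite matrices (or `omega_fit` objects) of equal
#'   dimension.
#' @return A non-negative scalar.
#' @examples
#' fmd_distance(diag(2), diag(2, 2)) # sqrt(2) * log(2)
#' @export
fmd_distance <- function(a, b) {
  a <- as_omega_matrix(a)
  b <- as_omega_matrix(b)
  if (!all(dim(a) == dim(b))) abort("dimension mismatch")
  lam <- eigen(solve(a, b), only.values = TRUE)$values
  lam <- Re(lam)
  if (any(lam <= 0)) abort("matrices must be positive definite")
  sqrt(sum(log(lam)^2))
}

#' Spectral decomposition of Omega
#'
#' Eigen-decomposition of the scaled covariance matrix; the eigenvectors
#' are the genomic principal components of population structure and the
#' variance fractions say how much of the genomic variation each explains.
#'
#' @param omega An `omega_fit`, `core_model_fit` or matrix.
#' @return A list with `eigenvalues`, `eigenvectors`,
#'   `variance_fraction` (sums to 1) and `scores` tibble (per-population
#'   PC coordinates).
#' @export
omega_svd <- function(omega) {
  pop_ids <- if (inherits(omega, "omega_fit")) omega$pop_ids else NULL
  m <- as_omega_matrix(omega)
  ev <- eigen(m, symmetric = TRUE)
  vf <- ev$values / sum(ev$values)
  scores <- as_tibble(ev$vectors, .name_repair = ~ paste0("PC", seq_along(.x)))
  scores <- dplyr::bind_cols(
    tibble(pop_id = if (is.null(pop_ids)) paste0("pop", seq_len(nrow(m))) else pop_ids),
    scores)
  list(eigenvalues = ev$values, eigenvectors = ev$vectors,
       variance_fraction = vf, scores = scores)
}

#' XtX differentiation statistic
#'
#' For each SNP, the posterior mean of the quadratic form
#' `a' Omega^-1 a` of the standardized population allele frequencies
#' `a = (alpha - pi) / sqrt(pi (1 - pi))` — the variance of the
#' standardized frequencies after whitening by Omega. Its neutral
#' expectation is close to the number of populations J, so it serves as a
#' structure-robust differentiation scan.
#'
#' @param fit A `core_model_fit` with per-SNP posterior second moments
#'   (`keep_cross = TRUE`).
#' @param omega The Omega used for whitening (defaults to the fit's
#'   posterior mean).
#' @return Numeric vector of per-SNP XtX values (non-negative).
#' @export
compute_xtx <- function(fit, omega = NULL) {
  if (is.null(fit$cross)) abort("fit lacks posterior cross-moments; rerun with keep_cross = TRUE")
  if (is.null(omega)) omega <- fit$omega
  lam <- solve(as_omega_matrix(omega))
  n <- dim(fit$cross)[3]
  vapply(seq_len(n), function(j) sum(lam * fit$cross[, , j]), 0.0)
}

#' SNPs in the upper tail of a statistic
#'
#' The `floor(fraction * N)` SNPs with the largest values; ties are broken
#' by genome order (earlier SNPs first).
#'
#' @param values Per-SNP statistic in genome order.
#' @param fraction Tail fraction in (0, 1), default 0.005.
#' @param ids Optional SNP identifiers (defaults to indices).
#' @return Identifiers of the tail SNPs.
#' @export
upper_tail <- function(values, fraction = 0.005, ids = seq_along(values)) {
  if (!length(values)) abort("empty input")
  stopifnot(fraction > 0, fraction < 1, length(ids) == length(values))
  k <- floor(fraction * length(values))
  if (k == 0) return(ids[integer(0)])
  ord <- order(-values, seq_along(values))
  ids[ord[seq_len(k)]]
}
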