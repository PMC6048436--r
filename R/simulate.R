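#' Covariance-matrix builders for simulations
#'
#' Helpers producing the scaled covariance matrix Omega of population
#' allele frequencies used by the simulator and the samplers.
#' `omega_identity()` gives independent populations;
#' `omega_compound_symmetry()` gives equicorrelated populations;
#' `omega_structured()` gives a single dominant axis of structure,
#' `Omega = scale * (I + lambda1 * u u')` with `u` a standardized linear
#' gradient across populations, so the leading eigenvector has distinct
#' loadings (a rank correlation with it is well defined) and explains
#' `pc1_fraction` of the total variance.
#'
#' @param n_pops Number of populations J.
#' @param rho Common correlation (compound symmetry), in (-1/(J-1), 1).
#' @param scale Multiplier applied to the whole matrix; the diagonal is
#'   the drift intensity of each population (an FST-like quantity).
#' @param pc1_fraction Fraction of total variance on the leading axis.
#' @return A J x J positive-definite matrix.
#' @export
omega_identity <- function(n_pops, scale = 1) diag(scale, n_pops)

#' @rdname omega_identity
#' @export
omega_compound_symmetry <- function(n_pops, rho, scale = 1) {
  m <- matrix(rho, n_pops, n_pops)
  diag(m) <- 1
  scale * m
}

#' @rdname omega_identity
#' @export
omega_structured <- function(n_pops, pc1_fraction = 0.5, scale = 0.15) {
  stopifnot(pc1_fraction > 1 / n_pops, pc1_fraction < 1)
  u <- seq_len(n_pops) - (n_pops + 1) / 2
  u <- u / sqrt(sum(u^2))
  # (1 + l) / (J + l) = pc1_fraction  =>  l = (J f - 1) / (1 - f)
  l <- (n_pops * pc1_fraction - 1) / (1 - pc1_fraction)
  scale * (diag(n_pops) + l * tcrossprod(u))
}

check_pos_def <- function(omega) {
  omega <- as.matrix(omega)
  if (!isSymmetric(omega, tol = 1e-8)) abort("omega must be symmetric")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("omega must be positive definite")
  omega
}

#' Simulation configuration
#'
#' Bundles the generative model's parameters. The defaults are the power
#' study's conditions: 168 populations, 10,000 SNPs of which 100 are
#' associated with the covariate at regression coefficient 0.1,
#' across-population frequencies drawn from Beta(2.78, 0.710) with a minor
#' allele frequency floor of 0.01, haploid pool sizes of 30 chromosomes and
#' read coverage 25x. `omega_spec` defaults to [omega_structured()], a
#' single dominant axis of population structure.
#'
#' @param n_pops,n_snps,n_assoc Design dimensions.
#' @param beta_effect Regression coefficient of associated SNPs on the
#'   standardized covariate (natural frequency scale).
#' @param beta_shape_a,beta_shape_b Beta shape parameters of the
#'   across-population allele frequency distribution.
#' @param maf_floor Lower bound on min(pi, 1 - pi).
#' @param omega_spec A J x J positive-definite matrix.
#' @param pool_sizes Haploid pool size(s), recycled over populations.
#' @param coverage Either a single coverage (used for every cell) or a
#'   vector of empirical coverages resampled per cell with replacement.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 168, n_snps = 10000, n_assoc = 100,
                       beta_effect = 0.1,
                       beta_shape_a = 2.78, beta_shape_b = 0.710,
                       maf_floor = 0.01,
                       omega_spec = omega_structured(n_pops),
                       pool_sizes = 30, coverage = 25) {
  stopifnot(n_assoc >= 0, n_assoc <= n_snps,
            maf_floor >= 0, maf_floor < 0.5)
  omega_spec <- check_pos_def(omega_spec)
  if (nrow(omega_spec) != n_pops) abort("omega dimension does not match n_pops")
  structure(list(
    n_pops = n_pops, n_snps = n_snps, n_assoc = n_assoc,
    beta_effect = beta_effect,
    beta_shape_a = beta_shape_a, beta_shape_b = beta_shape_b,
    maf_floor = maf_floor, omega_spec = omega_spec,
    pool_sizes = as.integer(rep_len(pool_sizes, n_pops)),
    coverage = as.integer(coverage)
  ), class = "sim_config")
}

#' Simulate a covariate with a target rank correlation to PC1 of Omega
#'
#' Mixes the rank-transformed leading eigenvector of `omega` with
#' independent Gaussian noise, `v(w) = w * u* + sqrt(1 - w^2) * eps`, and
#' tunes the mixing weight `w` by bisection until the empirical Spearman
#' correlation between the covariate and the leading eigenvector is within
#' `tolerance` of `target_rho`. The returned covariate is standardized
#' (mean 0, sd 1).
#'
#' @param omega Positive-definite covariance matrix of population allele
#'   frequencies (its leading eigenvector defines the major axis of
#'   population structure).
#' @param target_rho Target Spearman correlation in [0, 1).
#' @param seed Optional RNG seed.
#' @param tolerance Acceptable |achieved - target| (default 0.02).
#' @param max_restarts Fresh noise draws attempted before giving up.
#' @return A numeric covariate vector with attributes `achieved_rho` and
#'   `target_rho`.
#' @export
simulate_pc_correlated_covariate <- function(omega, target_rho,
                                             seed = NULL, tolerance = 0.02,
                                             max_restarts = 50) {
  stopifnot(target_rho >= 0, target_rho < 1)
  omega <- check_pos_def(omega)
  if (!is.null(seed)) set.seed(seed)
  u <- eigen(omega, symmetric = TRUE)$vectors[, 1]
  if (sd(u) < 1e-12) abort("leading eigenvector is constant; rank correlation undefined")
  base <- as.numeric(scale(rank(u)))
  J <- length(u)
  best <- NULL
  for (r in seq_len(max_restarts)) {
    eps <- as.numeric(scale(rnorm(J)))
    f <- function(w) {
      v <- w * base + sqrt(1 - w^2) * eps
      cor(v, u, method = "spearman")
    }
    lo <- -1; hi <- 1
    flo <- f(lo); fhi <- f(hi)
    if (!(flo <= target_rho && target_rho <= fhi)) next
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm - target_rho) <= tolerance) break
      if (fm < target_rho) lo <- mid else hi <- mid
    }
    ach <- f(mid)
    if (is.null(best) || abs(ach - target_rho) < abs(best$ach - target_rho)) {
      best <- list(w = mid, eps = eps, ach = ach)
    }
    if (abs(ach - target_rho) <= tolerance) break
  }
  if (is.null(best) || abs(best$ach - target_rho) > tolerance) {
    abort(paste0("covariate target rho ", target_rho,
                 " not reached; best achieved ",
                 if (is.null(best)) "none" else signif(best$ach, 4)))
  }
  v <- best$w * base + sqrt(1 - best$w^2) * best$eps
  v <- as.numeric(scale(v))
  structure(v, achieved_rho = best$ach, target_rho = target_rho)
}

#' Simulate a Pool-Seq dataset under the hierarchical model
#'
#' Per SNP j: an across-population frequency `pi_j ~ Beta(a, b)` truncated
#' so that `min(pi, 1 - pi) >= maf_floor`; population frequencies drawn
#' from a multivariate normal with mean `pi_j` (plus `beta * z` for
#' associated SNPs, `z` the standardized covariate) and covariance
#' `pi_j (1 - pi_j) * Omega`, clipped to [0, 1]; pool allele counts
#' binomial(haploid pool size, frequency); reference read counts
#' binomial(coverage, pooled frequency).
#'
#' @param config A [sim_config()].
#' @param covariate Standardized covariate vector of length `n_pops`
#'   (required when `n_assoc > 0`).
#' @param seed Optional RNG seed.
#' @return A list of class `gea_sim` with elements `counts`
#'   ([pool_counts]), `truth` (tibble of planted SNPs: `snp_id`,
#'   `beta_true`), `freq` (population frequency matrix after clipping to
#'   [0, 1]), `freq_latent` (the Gaussian layer before clipping, whose
#'   covariance is exactly `pi (1 - pi) Omega` — retained for moment
#'   diagnostics), `pi`, `omega`, and `n_clipped` (count of clipped
#'   cells, logged because clipping distorts the tails of strongly
#'   drifted SNPs).
#' @export
simulate_dataset <- function(config, covariate = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_snps
  J <- config$n_pops
  if (config$n_assoc > 0) {
    if (is.null(covariate)) abort("a covariate is required when n_assoc > 0")
    if (length(covariate) != J) abort("covariate length must equal n_pops")
  }
  # truncated Beta draw for across-population frequencies
  pi <- rbeta(n, config$beta_shape_a, config$beta_shape_b)
  bad <- which(pmin(pi, 1 - pi) < config$maf_floor)
  while (length(bad)) {
    pi[bad] <- rbeta(length(bad), config$beta_shape_a, config$beta_shape_b)
    bad <- bad[pmin(pi[bad], 1 - pi[bad]) < config$maf_floor]
  }
  L <- chol(config$omega_spec)
  E <- matrix(rnorm(n * J), n, J) %*% L
  alpha <- pi + sqrt(pi * (1 - pi)) * E
  assoc <- integer(0)
  if (config$n_assoc > 0) {
    assoc <- sort(sample.int(n, config$n_assoc))
    alpha[assoc, ] <- alpha[assoc, , drop = FALSE] +
      config$beta_effect * matrix(covariate, length(assoc), J, byrow = TRUE)
  }
  alpha_latent <- alpha
  n_clipped <- sum(alpha < 0 | alpha > 1)
  alpha <- pmin(pmax(alpha, 0), 1)
  size_mat <- matrix(config$pool_sizes, n, J, byrow = TRUE)
  y <- matrix(rbinom(n * J, size_mat, alpha), n, J)
  cov_mat <- if (length(config$coverage) == 1) {
    matrix(config$coverage, n, J)
  } else {
    matrix(sample(config$coverage, n * J, replace = TRUE), n, J)
  }
  ref <- matrix(rbinom(n * J, cov_mat, y / size_mat), n, J)
  alt <- cov_mat - ref
  counts <- pool_counts(
    tibble(chrom = "1", pos = 100L * seq_len(n)),
    ref, alt, pop_ids = paste0("pop", seq_len(J))
  )
  truth <- tibble(snp_id = counts$snps$snp_id[assoc],
                  beta_true = rep(config$beta_effect, length(assoc)))
  structure(list(counts = counts, truth = truth, freq = alpha,
                 freq_latent = alpha_latent, pi = pi,
                 omega = config$omega_spec, n_clipped = n_clipped,
                 covariate = covariate),
            class = "gea_sim")
}

#' Simulate a SNP annotation-category table
#'
#' Categories are drawn independently per SNP from `category_proportions`;
#' the default proportions are realistic genome-wide fractions of genic
#' variant classes (replacement 8.2%, synonymous 9.1%, intron 14.9%,
#' UTR 5.6%, intergenic 49.1%, intragenic 11.5%, remainder "other").
#' `planted_enrichment` multiplies one category's probability within a
#' designated SNP subset (renormalizing the rest), providing a positive
#' control for the enrichment tests.
#'
#' @param snp_ids SNP identifiers in genome order.
#' @param category_proportions Named vector of category probabilities
#'   summing to <= 1; any remainder goes to "other".
#' @param planted_enrichment Optional `list(category =, snp_ids =,
#'   factor =)`.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `snp_id`, `category`.
#' @export
simulate_annotation_table <- function(snp_ids,
                                      category_proportions = c(
                                        replacement = 0.082, synonymous = 0.091,
                                        intron = 0.149, UTR = 0.056,
                                        intergenic = 0.491, intragenic = 0.115),
                                      planted_enrichment = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  known <- c("intragenic", "intergenic", "UTR", "intron", "synonymous",
             "replacement", "other")
  if (!all(names(category_proportions) %in% known)) {
    abort(paste0("unknown category name: ",
                 setdiff(names(category_proportions), known)[1]))
  }
  p <- category_proportions
  if (sum(p) > 1 + 1e-12) abort("category proportions sum above 1")
  if (sum(p) < 1) p <- c(p, other = 1 - sum(p))
  cats <- names(p)
  draw <- sample(cats, length(snp_ids), replace = TRUE, prob = p)
  if (!is.null(planted_enrichment)) {
    pe <- planted_enrichment
    if (!pe$category %in% cats) abort(paste0("unknown category name: ", pe$category))
    idx <- match(pe$snp_ids, snp_ids)
    if (anyNA(idx)) abort("planted SNP ids not found")
    p2 <- p
    p2[pe$category] <- p2[pe$category] * pe$factor
    p2 <- p2 / sum(p2)
    draw[idx] <- sample(cats, length(idx), replace = TRUE, prob = p2)
  }
  tibble(snp_id = as.character(snp_ids), category = draw)
}
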