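#' Prune correlated covariates by rank correlation
#'
#' Greedy selection in preference order: a candidate is retained iff its
#' absolute Spearman correlation with every already-retained covariate is
#' at or below the threshold, so the retained set satisfies the pairwise
#' bound by construction. The preference order stands in for the
#' ecological judgement of which of two correlated variables to keep;
#' it defaults to column order.
#'
#' @param climate_table Data frame of covariates (locations x variables).
#' @param rho_threshold Maximum |Spearman rho| allowed between retained
#'   covariates (default 0.8).
#' @param preference_order Character vector ordering the candidates.
#' @return Character vector of retained covariate names.
#' @export
prune_covariates <- function(climate_table, rho_threshold = 0.8,
                             preference_order = names(climate_table)) {
  climate_table <- as.data.frame(climate_table)
  num <- vapply(climate_table, is.numeric, TRUE)
  climate_table <- climate_table[num]
  stopifnot(ncol(climate_table) >= 2)
  if (!all(names(climate_table) %in% preference_order)) {
    abort("preference order must cover all covariates")
  }
  consts <- names(climate_table)[vapply(climate_table, function(v) sd(v) == 0, TRUE)]
  if (length(consts)) {
    warn(paste0("excluding constant covariate(s): ", paste(consts, collapse = ", ")))
    climate_table <- climate_table[setdiff(names(climate_table), consts)]
  }
  kept <- character(0)
  for (nm in intersect(preference_order, names(climate_table))) {
    ok <- all(vapply(kept, function(k) {
      abs(cor(climate_table[[nm]], climate_table[[k]], method = "spearman")) <= rho_threshold
    }, TRUE))
    if (ok) kept <- c(kept, nm)
  }
  kept
}

#' Principal component analysis of climate space
#'
#' PCA on standardized climate variables across locations; used to place
#' sampled populations inside a broader climatic envelope.
#'
#' @param climate_table Locations x variables data frame (numeric).
#' @param groups Optional group labels per location (e.g. region).
#' @return A list of class `climate_space`: `scores` tibble (per-location
#'   PC coordinates plus `group`), `loadings`, `variance_fraction`.
#' @export
climate_pca <- function(climate_table, groups = NULL) {
  climate_table <- as.data.frame(climate_table)
  num <- vapply(climate_table, is.numeric, TRUE)
  m <- as.matrix(climate_table[num])
  if (nrow(m) < ncol(m)) warn("fewer locations than variables")
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  scores <- as_tibble(p$x)
  scores$group <- if (is.null(groups)) "all" else as.character(groups)
  structure(list(scores = scores, loadings = p$rotation,
                 variance_fraction = vf), class = "climate_space")
}

#' Fraction of a reference group's range covered by a subgroup
#'
#' `100 * (max - min score of the subgroup) / (max - min score of the
#' reference group)` on one principal component — how much of, say, the
#' European climate envelope the sampled region spans.
#'
#' @param space A `climate_space`.
#' @param subgroup,reference_group Group labels (reference may be a set).
#' @param component PC to use (default 1).
#' @return Percentage (0-100 for a nested subgroup).
#' @export
range_fraction <- function(space, subgroup, reference_group, component = 1) {
  sc <- space$scores[[paste0("PC", component)]]
  g <- space$scores$group
  sub <- sc[g %in% subgroup]
  ref <- sc[g %in% reference_group]
  stopifnot(length(sub) > 0, length(ref) > 0)
  dref <- diff(range(ref))
  if (dref == 0) abort("degenerate reference range")
  100 * diff(range(sub)) / dref
}

#' Spatial eigenvector basis (PCNM)
#'
#' Decomposes the spatial relationships among locations into orthogonal
#' eigenvectors of successive spatial grains (Principal Coordinates of
#' Neighbor Matrices): the Euclidean distance matrix is truncated at the
#' longest minimum-spanning-tree edge, distances beyond it are replaced
#' by four times the threshold, and the principal coordinates with
#' positive eigenvalues are returned in decreasing-eigenvalue order
#' (coarse to fine grain).
#'
#' @param coordinates Two-column matrix/data frame (e.g. longitude,
#'   latitude or projected x, y) with one row per location.
#' @return A list of class `spatial_basis`: `vectors` (location x
#'   component), `eigenvalues`, `threshold`.
#' @export
compute_pcnm <- function(coordinates) {
  xy <- as.matrix(coordinates)
  stopifnot(nrow(xy) >= 3)
  d <- stats::dist(xy)
  if (max(d) == 0) abort("all points are collocated")
  p <- vegan::pcnm(d)
  structure(list(vectors = unname(p$vectors),
                 eigenvalues = p$values[p$values > 0],
                 threshold = p$threshold),
            class = "spatial_basis")
}

#' Regress a climate variable on all spatial components
#'
#' Ordinary least squares of the variable on the full PCNM basis jointly,
#' with per-component t-test p-values corrected by Benjamini-Hochberg
#' across components (one family per variable).
#'
#' @param variable Numeric vector, one value per location.
#' @param basis A `spatial_basis` from [compute_pcnm()].
#' @param fdr_level Nominal FDR level (default 0.05).
#' @return A tibble with one row per component: `component`, `estimate`,
#'   `p_value`, `fdr_adjusted_p`, `significant`.
#' @export
pcnm_regression <- function(variable, basis, fdr_level = 0.05) {
  V <- basis$vectors
  stopifnot(length(variable) == nrow(V))
  if (ncol(V) > length(variable) - 1) abort("more components than locations - 1")
  df <- data.frame(y = variable, V)
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  comp <- rownames(sm) != "(Intercept)"
  out <- tibble(component = seq_len(sum(comp)),
                estimate = unname(sm[comp, "Estimate"]),
                p_value = unname(sm[comp, "Pr(>|t|)"]))
  out$fdr_adjusted_p <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr_adjusted_p <= fdr_level
  out
}

#' Regression of genomic PC coordinates on geography
#'
#' OLS of a genomic principal component on latitude, longitude and their
#' interaction; reports coefficients, t-values and the adjusted R
#' squared.
#'
#' @param pc_scores Per-population coordinates on one genomic PC.
#' @param latitude,longitude Decimal-degree coordinates.
#' @return A list with `coefficients` tibble (`term`, `estimate`,
#'   `t_value`, `p_value`) and `adj_r_squared`.
#' @export
genomic_geography_regression <- function(pc_scores, latitude, longitude) {
  df <- data.frame(y = pc_scores, latitude = latitude, longitude = longitude)
  fit <- lm(y ~ latitude * longitude, data = df)
  if (any(is.na(coef(fit)))) abort("degenerate (collinear) geographic design")
  sm <- summary(fit)
  co <- sm$coefficients
  list(coefficients = tibble(term = rownames(co),
                             estimate = unname(co[, "Estimate"]),
                             t_value = unname(co[, "t value"]),
                             p_value = unname(co[, "Pr(>|t|)"])),
       adj_r_squared = sm$adj.r.squared)
}
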