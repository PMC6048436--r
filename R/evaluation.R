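#' Classification rates at a score threshold
#'
#' Calls every SNP with `score >= threshold` associated and reports the
#' true positive rate (power: true positives / truly associated), false
#' positive rate (false positives / truly non-associated) and false
#' discovery rate (false positives / called). When nothing is called the
#' FDR is reported as 0 by convention and flagged.
#'
#' @param scores Per-SNP scores (e.g. BF in deciban).
#' @param truth Logical/0-1 vector of true association status.
#' @param threshold Calling threshold.
#' @return A one-row tibble: `threshold`, `tpr`, `fpr`, `fdr`,
#'   `fdr_defined`.
#' @export
confusion_at_threshold <- function(scores, truth, threshold) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  if (!any(truth)) abort("no positives in truth; TPR undefined")
  called <- scores >= threshold
  tp <- sum(called & truth)
  fp <- sum(called & !truth)
  tibble(threshold = threshold,
         tpr = tp / sum(truth),
         fpr = fp / sum(!truth),
         fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
         fdr_defined = tp + fp > 0)
}

#' ROC and precision-recall curves with AUC
#'
#' Sweeps every achieved score threshold, computing TPR, FPR and FDR at
#' each; the ROC curve plots TPR against FPR and the PR curve plots
#' precision (1 - FDR) against TPR. Both areas use the trapezoid rule on
#' the achieved-threshold grid.
#'
#' @param scores Per-SNP scores.
#' @param truth Logical/0-1 association status (both classes present).
#' @return An object of class `roc_pr`: `curve` tibble (`threshold`,
#'   `tpr`, `fpr`, `fdr`), `roc_auc`, `pr_auc`.
#' @examples
#' roc_pr_curves(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$roc_auc # 0.75
#' @export
roc_pr_curves <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) abort("both classes must be present")
  ord <- order(-scores)
  s <- scores[ord]
  t <- truth[ord]
  tp <- cumsum(t)
  fp <- cumsum(!t)
  # collapse ties: keep the last index of each distinct score
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]; thr <- s[keep]
  P <- sum(t); Ng <- sum(!t)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / Ng)
  prec <- c(1, tp / (tp + fp))
  curve <- tibble(threshold = c(Inf, thr), tpr = tpr, fpr = fpr,
                  fdr = 1 - prec)
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(curve = curve,
                 roc_auc = trap(fpr, tpr),
                 pr_auc = trap(tpr, prec)),
            class = "roc_pr")
}

#' @export
print.roc_pr <- function(x, ...) {
  cat("<roc_pr> ROC AUC ", signif(x$roc_auc, 4), "; PR AUC ",
      signif(x$pr_auc, 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.roc_pr <- function(x, ...) tibble(roc_auc = x$roc_auc, pr_auc = x$pr_auc)

#' @export
tidy.roc_pr <- function(x, ...) x$curve

#' ROC / precision-recall plot
#' @param object A `roc_pr`.
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_pr <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  df <- object$curve
  if (which == "roc") {
    ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = 2, colour = "grey") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$tpr, 1 - .data$fdr)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "true positive rate (recall)", y = "precision") +
      ggplot2::theme_minimal()
  }
}

#' Power study over covariate-structure correlation levels
#'
#' The full simulation loop of the power analysis: for each target rank
#' correlation `rho` between the covariate and the leading axis of
#' population structure, simulate a covariate, simulate `n_replicates`
#' Pool-Seq datasets with planted associated SNPs, scan each under the
#' AUX model using the true (generating) Omega, pool the replicate scores
#' per `rho` by concatenation, and evaluate ROC / PR curves against the
#' planted truth.
#'
#' @param rho_levels Target Spearman correlations with PC1.
#' @param n_replicates Simulated datasets per level.
#' @param config A [sim_config()] (its `omega_spec` is both the generator
#'   and the scan's Omega).
#' @param settings MCMC schedule for the scans.
#' @param seed Root seed; per-stage seeds are spawned deterministically.
#' @return A list of class `power_study`: `auc` tibble (one row per rho:
#'   `rho`, `achieved_rho`, `roc_auc`, `pr_auc`), `curves` (list of
#'   `roc_pr` per rho), `scores` (pooled tibble).
#' @export
power_study <- function(rho_levels, n_replicates, config,
                        settings = mcmc_settings_desk(), seed = 1) {
  stopifnot(length(rho_levels) >= 1, n_replicates >= 1)
  seeds <- spawn_seeds(seed, length(rho_levels) * (n_replicates + 1) + 1)
  si <- 0
  next_seed <- function() { si <<- si + 1; seeds[si] }
  curves <- list()
  auc <- list()
  pooled <- list()
  for (k in seq_along(rho_levels)) {
    rho <- rho_levels[k]
    z <- simulate_pc_correlated_covariate(config$omega_spec, rho,
                                          seed = next_seed())
    scores <- list()
    for (r in seq_len(n_replicates)) {
      s <- next_seed()
      sim <- simulate_dataset(config, covariate = as.numeric(z), seed = s)
      scan <- run_aux_scan(sim$counts, config$omega_spec, as.numeric(z),
                           pool_sizes = config$pool_sizes,
                           settings = settings, seed = s + 1)
      res <- tidy(scan)
      scores[[r]] <- tibble(rho = rho, replicate = r,
                            bf_db = res$bf_db,
                            truth = res$snp_id %in% sim$truth$snp_id)
    }
    sc <- dplyr::bind_rows(scores)
    cv <- roc_pr_curves(sc$bf_db, sc$truth)
    curves[[as.character(rho)]] <- cv
    pooled[[k]] <- sc
    auc[[k]] <- tibble(rho = rho,
                       achieved_rho = attr(z, "achieved_rho"),
                       roc_auc = cv$roc_auc, pr_auc = cv$pr_auc)
  }
  structure(list(auc = dplyr::bind_rows(auc), curves = curves,
                 scores = dplyr::bind_rows(pooled),
                 config = config, seed = seed),
            class = "power_study")
}

#' @export
print.power_study <- function(x, ...) {
  cat("<power_study>\n")
  print(x$auc)
  invisible(x)
}

#' @export
tidy.power_study <- function(x, ...) x$auc

#' AUC against structure-covariate correlation
#' @param object A `power_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_study <- function(object, ...) {
  df <- tidyr::pivot_longer(object$auc, c("roc_auc", "pr_auc"),
                            names_to = "metric", values_to = "auc")
  ggplot2::ggplot(df, ggplot2::aes(.data$rho, .data$auc,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "covariate-PC1 Spearman correlation",
                  y = "area under the curve") +
    ggplot2::theme_minimal()
}
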