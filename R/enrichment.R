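#' Fold enrichment of an annotation category in a SNP tail
#'
#' `FE = (s_a / s) / (S_a / S)`: the proportion of tail SNPs in the
#' category relative to the genome-wide proportion, where `s` is the tail
#' size, `s_a` the tail SNPs in the category, `S` the annotated universe
#' and `S_a` the universe SNPs in the category. FE = 1 when the tail's
#' composition matches the background.
#'
#' @param top SNP ids in the selected tail (subset of `annot$snp_id`).
#' @param annot Annotation tibble (`snp_id`, `category`).
#' @param category Category to test.
#' @param covariate Optional label carried into the result.
#' @return A one-row tibble: counts, `fold_enrichment`, `direction`.
#' @examples
#' annot <- tibble::tibble(snp_id = as.character(1:10000),
#'                         category = rep(c("synonymous", "other"), c(1000, 9000)))
#' fold_enrichment_annotation(as.character(1:200)[1:40 * 5],
#'                            annot, "synonymous")
#' @export
fold_enrichment_annotation <- function(top, annot, category,
                                       covariate = NA_character_) {
  if (!all(top %in% annot$snp_id)) abort("tail SNPs missing from annotation universe")
  S <- nrow(annot)
  S_a <- sum(annot$category == category)
  s <- length(top)
  s_a <- sum(annot$category[match(top, annot$snp_id)] == category)
  fe <- if (S_a == 0 || s == 0) NA_real_ else (s_a / s) / (S_a / S)
  if (S_a == 0) warn(paste0("category ", category, " absent from the universe; FE undefined"))
  tibble(covariate = covariate, category = category,
         s = s, s_a = s_a, S = S, S_a = S_a,
         fold_enrichment = fe,
         direction = ifelse(is.na(fe) | fe >= 1, "over", "under"))
}

#' Fold enrichment of one SNP tail in another
#'
#' Overlap enrichment of the top-BF tail within the top-XtX tail:
#' `FE = (n_a / n) / (N_a / N)` with `n` the XtX tail size, `N_a` the BF
#' tail size, `n_a` their intersection and `N` the SNP universe size.
#'
#' @param top_bf,top_xtx SNP id sets (tails of the two statistics).
#' @param N Number of SNPs in the universe.
#' @param covariate Optional label carried into the result.
#' @return A one-row tibble with counts and `fold_enrichment`.
#' @export
fold_enrichment_xtx <- function(top_bf, top_xtx, N,
                                covariate = NA_character_) {
  n <- length(top_xtx)
  N_a <- length(top_bf)
  n_a <- length(intersect(top_bf, top_xtx))
  fe <- if (n == 0 || N_a == 0) NA_real_ else (n_a / n) / (N_a / N)
  if (n == 0 || N_a == 0) warn("empty tail; FE undefined")
  tibble(covariate = covariate, category = "XtX tail",
         n = n, n_a = n_a, N = N, N_a = N_a,
         fold_enrichment = fe,
         direction = ifelse(is.na(fe) | fe >= 1, "over", "under"))
}

rotate_vec <- function(v, offset) {
  n <- length(v)
  offset <- offset %% n
  if (offset == 0) v else c(v[(n - offset + 1):n], v[1:(n - offset)])
}

#' Circular-permutation test for fold enrichment
#'
#' Builds a null distribution for an observed fold enrichment by rotating
#' the tail-membership indicator along the concatenated genome by random
#' offsets, keeping the per-SNP attribute labels fixed. Rotation (rather
#' than shuffling) preserves runs of linked SNPs, so the null accounts
#' for local autocorrelation (LD) in both vectors. The p-value uses the
#' add-one estimator `p = (1 + #{FE_null >= FE_obs}) / (1 + n_perm)` for
#' over-representation (mirrored for under-representation), so it is
#' never exactly zero.
#'
#' @param observed_fe Observed fold enrichment.
#' @param tail_indicator Logical/0-1 vector in genome order (tail
#'   membership).
#' @param attribute Per-SNP labels in the same genome order: either a
#'   logical/0-1 vector (category membership, annotation test) or for the
#'   two-tail test the other tail's indicator.
#' @param n_perm Number of rotations (default 10000).
#' @param direction `"over"` or `"under"`.
#' @param offsets Optional explicit offsets (e.g. `seq_len(N - 1)` for
#'   exhaustive enumeration); otherwise drawn uniformly from 1..N-1,
#'   with replacement (with a warning) when `n_perm > N - 1`.
#' @param seed Optional RNG seed.
#' @return A list with `p_perm`, `null_fe` (the null FE values) and
#'   `n_perm`.
#' @export
circular_permutation_test <- function(observed_fe, tail_indicator, attribute,
                                      n_perm = 10000,
                                      direction = c("over", "under"),
                                      offsets = NULL, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(tail_indicator) == length(attribute), n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- length(tail_indicator)
  ti <- as.logical(tail_indicator)
  at <- as.logical(attribute)
  if (is.null(offsets)) {
    if (n_perm > N - 1) {
      warn("offset space smaller than n_perm; sampling offsets with replacement")
      offsets <- sample.int(N - 1, n_perm, replace = TRUE)
    } else {
      offsets <- sample.int(N - 1, n_perm, replace = FALSE)
    }
  }
  s <- sum(ti)
  Sa <- sum(at)
  fe_at_offset <- function(off) {
    sa <- sum(rotate_vec(ti, off) & at)
    (sa / s) / (Sa / N)
  }
  null_fe <- vapply(offsets, fe_at_offset, 0.0)
  hits <- if (direction == "over") sum(null_fe >= observed_fe)
          else sum(null_fe <= observed_fe)
  list(p_perm = (1 + hits) / (1 + length(offsets)),
       null_fe = null_fe, n_perm = length(offsets))
}

#' Annotation-category enrichment scan with permutation p-values
#'
#' Runs [fold_enrichment_annotation()] for every category (or a chosen
#' set) against the given tail and attaches circular-permutation
#' p-values.
#'
#' @param top Tail SNP ids.
#' @param annot Annotation tibble in genome order (`snp_id`, `category`).
#' @param categories Categories to test (default: all present).
#' @param n_perm Rotations per category.
#' @param covariate Label carried into the result.
#' @param seed Optional RNG seed.
#' @return A tibble, one row per category, with counts, FE, `p_perm`.
#' @export
enrichment_scan <- function(top, annot, categories = NULL, n_perm = 10000,
                            covariate = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(categories)) categories <- sort(unique(annot$category))
  ti <- annot$snp_id %in% top
  purrr::map_dfr(categories, function(cat) {
    row <- fold_enrichment_annotation(top, annot, cat, covariate)
    if (is.na(row$fold_enrichment)) {
      row$p_perm <- NA_real_
      return(row)
    }
    pt <- circular_permutation_test(row$fold_enrichment, ti,
                                    annot$category == cat, n_perm,
                                    direction = row$direction)
    row$p_perm <- pt$p_perm
    row
  })
}

#' Benjamini-Hochberg correction over an enrichment family
#'
#' Adjusts the permutation p-values of a family of enrichment tests
#' (e.g. all categories x climate variables) and flags significance at
#' the nominal FDR level.
#'
#' @param results Tibble with a `p_perm` column.
#' @param level Nominal FDR level (default 0.05).
#' @return `results` with `fdr_adjusted_p` and `significant` columns.
#' @export
adjust_enrichment_fdr <- function(results, level = 0.05) {
  if (!nrow(results)) abort("no enrichment results to adjust")
  results$fdr_adjusted_p <- p.adjust(results$p_perm, method = "BH")
  results$significant <- !is.na(results$fdr_adjusted_p) &
    results$fdr_adjusted_p <= level
  results
}
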