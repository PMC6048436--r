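test_that("fold enrichment arithmetic matches hand computations", {
  # annotation test: s = 200, s_a = 40, S = 10000, S_a = 1000 -> FE = 2
  annot <- tibble::tibble(
    snp_id = as.character(1:10000),
    category = rep(c("replacement", "other"), c(1000, 9000)))
  top <- c(as.character(1:40), as.character(2000:2159))
  row <- fold_enrichment_annotation(top, annot, "replacement")
  expect_equal(row$fold_enrichment, 2.0)
  expect_equal(c(row$s, row$s_a, row$S, row$S_a), c(200, 40, 10000, 1000))

  # two-tail overlap: both tails 50 of 10000, overlap 10 -> FE = 40
  row2 <- fold_enrichment_xtx(as.character(1:50), as.character(41:90), 10000)
  expect_equal(row2$fold_enrichment, 40.0)
  expect_equal(c(row2$n, row2$n_a, row2$N, row2$N_a), c(50, 10, 10000, 50))
})

test_that("random tails give FE near 1 and FE identities hold", {
  set.seed(3)
  annot <- simulate_annotation_table(as.character(1:20000), seed = 3)
  top <- sample(annot$snp_id, 2000)
  rows <- purrr::map_dfr(unique(annot$category), function(cc)
    fold_enrichment_annotation(top, annot, cc))
  expect_equal(sum(rows$s_a), rows$s[1]) # categories partition the tail
  # background-weighted FE averages to 1 over categories
  expect_equal(sum(rows$fold_enrichment * rows$S_a / rows$S), 1,
               tolerance = 1e-12)
  expect_true(all(abs(rows$fold_enrichment - 1) < 0.25))
})

test_that("zero-offset rotation reproduces the observed fold enrichment", {
  set.seed(9)
  ti <- sample(c(TRUE, FALSE), 400, replace = TRUE, prob = c(0.05, 0.95))
  at <- sample(c(TRUE, FALSE), 400, replace = TRUE, prob = c(0.3, 0.7))
  fe_obs <- (sum(ti & at) / sum(ti)) / (sum(at) / 400)
  pt <- circular_permutation_test(fe_obs, ti, at, offsets = 0)
  expect_equal(pt$null_fe, fe_obs)
})

test_that("rotation null matches exhaustive enumeration on small instances", {
  set.seed(11)
  N <- 18
  ti <- c(rep(TRUE, 3), rep(FALSE, N - 3))
  at <- sample(c(TRUE, FALSE), N, replace = TRUE)
  fe_obs <- (sum(ti & at) / 3) / (sum(at) / N)
  # oracle: recompute FE for every rotation by explicit index shifting
  oracle <- vapply(1:(N - 1), function(off) {
    idx <- ((seq_len(N) - 1 - off) %% N) + 1
    tir <- ti[idx]
    (sum(tir & at) / sum(tir)) / (sum(at) / N)
  }, 0.0)
  pt <- circular_permutation_test(fe_obs, ti, at, offsets = 1:(N - 1))
  expect_equal(sort(pt$null_fe), sort(oracle))
  # p-values invariant to joint rotation of both vectors
  shift <- 7
  idx <- ((seq_len(N) - 1 - shift) %% N) + 1
  pt2 <- circular_permutation_test(fe_obs, ti[idx], at[idx],
                                   offsets = 1:(N - 1))
  expect_equal(sort(pt2$null_fe), sort(pt$null_fe))
  expect_equal(pt2$p_perm, pt$p_perm)
})

test_that("rotation null is wider than an independent shuffle on clustered data", {
  set.seed(17)
  N <- 1000
  # clustered tail (one contiguous block) and clustered category
  ti <- rep(FALSE, N); ti[101:150] <- TRUE
  at <- rep(FALSE, N); at[c(120:220, 700:800)] <- TRUE
  fe_obs <- (sum(ti & at) / sum(ti)) / (sum(at) / N)
  rot <- circular_permutation_test(fe_obs, ti, at, n_perm = 800, seed = 1)
  shuf <- replicate(800, {
    tis <- sample(ti)
    (sum(tis & at) / sum(ti)) / (sum(at) / N)
  })
  expect_gt(var(rot$null_fe), var(shuf))
})

test_that("offsets are resampled with a warning when the space is small", {
  ti <- c(TRUE, TRUE, rep(FALSE, 8))
  at <- rep(c(TRUE, FALSE), 5)
  expect_warning(
    circular_permutation_test(1, ti, at, n_perm = 50, seed = 2),
    "replacement")
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(23)
  pvals <- replicate(200, {
    N <- 400
    at <- sample(c(TRUE, FALSE), N, replace = TRUE, prob = c(0.3, 0.7))
    ti <- rep(FALSE, N)
    ti[sample.int(N, 40)] <- TRUE
    fe <- (sum(ti & at) / 40) / (sum(at) / N)
    circular_permutation_test(fe, ti, at, n_perm = 199)$p_perm
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment over the enrichment family matches p.adjust by hand", {
  res <- tibble::tibble(p_perm = c(0.01, 0.02, 0.03, 0.04))
  adj <- adjust_enrichment_fdr(res)
  expect_equal(adj$fdr_adjusted_p, rep(0.04, 4))
  one <- adjust_enrichment_fdr(tibble::tibble(p_perm = 0.2))
  expect_equal(one$fdr_adjusted_p, 0.2)
  all1 <- adjust_enrichment_fdr(tibble::tibble(p_perm = rep(1, 5)))
  expect_true(all(all1$fdr_adjusted_p == 1))
})
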