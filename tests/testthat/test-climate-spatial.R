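test_that("greedy Spearman pruning keeps the preferred uncorrelated set", {
  set.seed(2)
  n <- 100
  v1 <- rnorm(n)
  tab <- data.frame(v1 = v1, v2 = v1 + rnorm(n, sd = 0.05), v3 = rnorm(n))
  expect_equal(prune_covariates(tab), c("v1", "v3"))
  expect_equal(prune_covariates(tab, preference_order = c("v2", "v1", "v3")),
               c("v2", "v3"))
  # all pairwise below threshold: everything retained
  ind <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(prune_covariates(ind), c("a", "b", "c"))
  # retained set satisfies the bound by construction
  set.seed(4)
  big <- as.data.frame(matrix(rnorm(n * 8), n) %*% matrix(rnorm(64), 8))
  kept <- prune_covariates(big, rho_threshold = 0.5)
  cm <- cor(big[kept], method = "spearman")
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.5))
  # constants are excluded with a warning
  expect_warning(k2 <- prune_covariates(cbind(ind, k = 1)), "constant")
  expect_false("k" %in% k2)
})

test_that("climate PCA fractions behave on degenerate and isotropic input", {
  n <- 1000
  x <- rnorm(n)
  two <- data.frame(a = x, b = 2 * x + 3)
  cs <- climate_pca(two)
  expect_equal(cs$variance_fraction[1], 1)
  set.seed(6)
  iso <- as.data.frame(matrix(rnorm(n * 4), n))
  fr <- climate_pca(iso)$variance_fraction
  expect_equal(fr, rep(0.25, 4), tolerance = 0.2)
  expect_equal(sum(fr), 1)
})

test_that("range fractions are ratios of PC score extents", {
  sc <- climate_pca(data.frame(a = c(0, 1, 2, 10), b = c(0, 1, 2, 10)),
                    groups = c("sub", "sub", "sub", "ref"))
  expect_equal(range_fraction(sc, "sub", c("sub", "ref")), 20,
               tolerance = 1e-6)
  expect_equal(range_fraction(sc, c("sub", "ref"), c("sub", "ref")), 100)
})

test_that("PCNM components are orthogonal and match a direct eigen oracle", {
  xy <- cbind(seq_len(10), 0) # 10 points on a line, unit spacing
  basis <- compute_pcnm(xy)
  V <- basis$vectors
  # pairwise orthogonality
  g <- crossprod(V)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # grains order coarse to fine: component k waves k times along the line
  sign_changes <- apply(V, 2, function(v) sum(diff(sign(v)) != 0))
  expect_equal(sign_changes, seq_len(ncol(V)))
  # oracle: explicit truncated-distance PCoA on the same points
  d <- as.matrix(dist(xy))
  thr <- basis$threshold
  d[d > thr] <- 4 * thr
  n <- nrow(d)
  H <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * H %*% (d^2) %*% H
  ev <- eigen(G, symmetric = TRUE)
  keep <- ev$values > sqrt(.Machine$double.eps) * max(ev$values)
  expect_equal(length(basis$eigenvalues), sum(keep))
  expect_equal(basis$eigenvalues, ev$values[keep], tolerance = 1e-6)
  # spaces agree: every oracle eigenvector is reproduced up to sign/scale
  for (k in seq_len(sum(keep))) {
    expect_gt(abs(cor(V[, k], ev$vectors[, k])), 0.999)
  }
  expect_error(compute_pcnm(matrix(1, 5, 2)), "collocated")
})

test_that("pcnm_regression recovers a planted component and calibrates", {
  set.seed(8)
  xy <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  basis <- compute_pcnm(xy)
  y <- 3 * basis$vectors[, 2] + rnorm(40, sd = 0.01)
  out <- pcnm_regression(y, basis)
  expect_true(out$significant[2])
  expect_equal(sum(out$significant), 1L)
  expect_equal(out$estimate[2], 3, tolerance = 0.05)
  # pure-noise calibration: BH keeps the false-positive rate at bay
  set.seed(9)
  fp <- replicate(100, {
    any(pcnm_regression(rnorm(40), basis)$significant)
  })
  expect_lte(mean(fp), 0.1)
  # p-values invariant to affine rescaling of the variable
  out2 <- pcnm_regression(10 * y + 5, basis)
  expect_equal(out2$p_value, out$p_value, tolerance = 1e-9)
})

test_that("geography regression recovers planted latitude effects", {
  set.seed(10)
  lat <- runif(80, 42, 45)
  lon <- runif(80, 0, 3)
  indep <- rnorm(80)
  g0 <- genomic_geography_regression(indep, lat, lon)
  expect_lt(abs(g0$adj_r_squared), 0.1)
  y <- 0.5 * lat + rnorm(80, sd = 0.05)
  g1 <- genomic_geography_regression(y, lat, lon)
  co <- g1$coefficients
  expect_lt(co$p_value[co$term == "latitude"], 1e-6)
  expect_equal(co$estimate[co$term == "latitude"], 0.5, tolerance = 0.2)
  expect_gt(g1$adj_r_squared, 0.9)
  expect_error(genomic_geography_regression(y, lat, lat), "degenerate")
})
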