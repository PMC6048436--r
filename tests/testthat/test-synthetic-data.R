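test_that("identical seed and config give bit-identical datasets", {
  cfg <- sim_config(n_pops = 6, n_snps = 200, n_assoc = 10,
                    omega_spec = omega_structured(6))
  z <- simulate_pc_correlated_covariate(cfg$omega_spec, 0.3, seed = 5)
  a <- simulate_dataset(cfg, as.numeric(z), seed = 99)
  b <- simulate_dataset(cfg, as.numeric(z), seed = 99)
  expect_identical(a$counts$ref, b$counts$ref)
  expect_identical(a$counts$alt, b$counts$alt)
  expect_identical(a$truth, b$truth)
  expect_identical(a$freq, b$freq)
})

test_that("read counts satisfy ref + alt = coverage and truth size", {
  cfg <- sim_config(n_pops = 5, n_snps = 100, n_assoc = 0,
                    omega_spec = omega_identity(5, 0.15))
  sim <- simulate_dataset(cfg, seed = 2)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(coverage(sim$counts) == 25L))
  cfg2 <- sim_config(n_pops = 5, n_snps = 500, n_assoc = 30,
                     omega_spec = omega_identity(5, 0.15))
  z <- rnorm(5); z <- as.numeric(scale(z))
  sim2 <- simulate_dataset(cfg2, z, seed = 3)
  expect_equal(nrow(sim2$truth), 30L)
  expect_true(all(sim2$truth$snp_id %in% sim2$counts$snps$snp_id))
  expect_equal(sim2$truth$beta_true, rep(0.1, 30))
})

test_that("across-population frequencies respect the maf floor", {
  cfg <- sim_config(n_pops = 4, n_snps = 2000, n_assoc = 0,
                    omega_spec = omega_identity(4, 0.15), maf_floor = 0.05)
  sim <- simulate_dataset(cfg, seed = 8)
  expect_true(all(pmin(sim$pi, 1 - sim$pi) >= 0.05))
})

test_that("standardized latent frequencies reproduce Omega moments", {
  # identity Omega: off-diagonal correlations vanish
  J <- 6
  cfg <- sim_config(n_pops = J, n_snps = 20000, n_assoc = 0,
                    omega_spec = omega_identity(J))
  sim <- simulate_dataset(cfg, seed = 4)
  a <- (sim$freq_latent - sim$pi) / sqrt(sim$pi * (1 - sim$pi))
  cc <- cor(a)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.01)

  # structured Omega: empirical covariance converges in Frobenius norm
  omS <- omega_structured(J)
  for (n in c(500, 20000)) {
    cfgS <- sim_config(n_pops = J, n_snps = n, n_assoc = 0, omega_spec = omS)
    simS <- simulate_dataset(cfgS, seed = 4)
    aS <- (simS$freq_latent - simS$pi) / sqrt(simS$pi * (1 - simS$pi))
    assign(paste0("fro", n), norm(cov(aS) - omS, "F"))
  }
  expect_lt(fro20000, fro500)
  expect_lt(fro20000, 0.02)
})

test_that("planted SNPs carry the configured regression slope", {
  J <- 16
  om <- omega_identity(J, 0.15)
  cfg <- sim_config(n_pops = J, n_snps = 3000, n_assoc = 1500,
                    beta_effect = 0.1, omega_spec = om, maf_floor = 0.2)
  z <- as.numeric(scale(rnorm(J)))
  sim <- simulate_dataset(cfg, z, seed = 10)
  assoc <- sim$counts$snps$snp_id %in% sim$truth$snp_id
  slope <- function(rows) {
    mean(apply(sim$freq_latent[rows, ], 1, function(f) coef(lm(f ~ z))[2]))
  }
  expect_equal(slope(assoc), 0.1, tolerance = 0.05)
  expect_equal(slope(!assoc), 0, tolerance = 0.02)
})

test_that("covariate generator hits Spearman targets against PC1", {
  om <- omega_structured(32)
  u <- eigen(om, symmetric = TRUE)$vectors[, 1]
  # independence target
  z0 <- simulate_pc_correlated_covariate(om, 0, seed = 1)
  expect_lte(abs(spearman_oracle(as.numeric(z0), u)), 0.02)
  expect_equal(mean(z0), 0, tolerance = 1e-12)
  expect_equal(sd(z0), 1, tolerance = 1e-12)

  # the ten-level grid used in the power design, achieved values monotone
  grid <- seq(0, 0.9, by = 0.1)
  ach <- vapply(seq_along(grid), function(i) {
    z <- simulate_pc_correlated_covariate(om, grid[i], seed = 100 + i)
    spearman_oracle(as.numeric(z), u)
  }, 0.0)
  expect_true(all(abs(ach - grid) <= 0.02))
  expect_true(all(diff(ach) > 0))

  # strong-correlation target, checked with the independent rank oracle
  om168 <- omega_structured(168)
  z9 <- simulate_pc_correlated_covariate(om168, 0.9, seed = 42)
  r <- spearman_oracle(as.numeric(z9),
                       eigen(om168, symmetric = TRUE)$vectors[, 1])
  expect_gte(r, 0.88)
  expect_lte(r, 0.92)
})

test_that("annotation simulator reproduces proportions and planted excess", {
  ids <- as.character(seq_len(20000))
  tab <- simulate_annotation_table(ids, seed = 6)
  frac <- table(tab$category) / length(ids)
  expect_equal(unname(frac[["intergenic"]]), 0.491, tolerance = 0.02)
  expect_equal(unname(frac[["replacement"]]), 0.082, tolerance = 0.05)
  expect_error(simulate_annotation_table(ids, c(nonsense = 0.5)),
               "unknown category")

  sub <- ids[1:2000]
  tab2 <- simulate_annotation_table(
    ids, planted_enrichment = list(category = "replacement",
                                   snp_ids = sub, factor = 2),
    seed = 6)
  in_sub <- tab2$snp_id %in% sub
  f_sub <- mean(tab2$category[in_sub] == "replacement")
  f_bg <- mean(tab2$category[!in_sub] == "replacement")
  expect_equal(f_sub / f_bg, 2 * 0.082 / (1 + 0.082) / 0.082,
               tolerance = 0.35)
  expect_gt(f_sub, 1.4 * f_bg)
})
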