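test_that("standardize_covariate is exact, idempotent, and guards constants", {
  expect_equal(standardize_covariate(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize_covariate(rnorm(20))
  expect_equal(standardize_covariate(z), z, tolerance = 1e-12)
  expect_error(standardize_covariate(rep(2, 5)), "constant")
})

test_that("aux scan demands a standardized covariate and matched dims", {
  sim <- simulate_dataset(sim_config(n_pops = 5, n_snps = 50, n_assoc = 0,
                                     omega_spec = omega_identity(5, 0.15)),
                          seed = 1)
  expect_error(run_aux_scan(sim$counts, diag(5), rep(1, 5) * 2,
                            pool_sizes = 30), "standardized")
  expect_error(run_aux_scan(sim$counts, diag(4),
                            as.numeric(scale(rnorm(5))), pool_sizes = 30),
               "dimension")
})

test_that("spike-and-slab scan separates planted from neutral SNPs", {
  J <- 16
  om <- omega_structured(J)
  cfg <- sim_config(n_pops = J, n_snps = 1200, n_assoc = 15,
                    beta_effect = 0.15, omega_spec = om)
  z <- simulate_pc_correlated_covariate(om, 0, seed = 21)
  sim <- simulate_dataset(cfg, as.numeric(z), seed = 22)
  scan <- run_aux_scan(sim$counts, om, as.numeric(z), pool_sizes = 30,
                       settings = mcmc_settings_desk(), seed = 23)
  res <- tidy(scan)
  assoc <- res$snp_id %in% sim$truth$snp_id
  expect_gt(median(res$bf_db[assoc]), quantile(res$bf_db[!assoc], 0.95))
  # strongly supported effects carry the planted (positive) sign
  strong <- assoc & res$pip > 0.5
  expect_gte(mean(sign(res$beta[strong]) == 1), 0.95)
  # PIP bounded and BF finite
  expect_true(all(res$pip >= scan$pip_cap & res$pip <= 1 - scan$pip_cap))
  expect_true(all(is.finite(res$bf_db)))
  # determinism
  scan2 <- run_aux_scan(sim$counts, om, as.numeric(z), pool_sizes = 30,
                        settings = mcmc_settings_desk(), seed = 23)
  expect_identical(tidy(scan2)$bf_db, res$bf_db)
})

test_that("BF ranking is invariant to affine rescaling of the raw covariate", {
  J <- 10
  om <- omega_identity(J, 0.15)
  cfg <- sim_config(n_pops = J, n_snps = 300, n_assoc = 10,
                    omega_spec = om, maf_floor = 0.1)
  raw <- rnorm(J)
  sim <- simulate_dataset(cfg, standardize_covariate(raw), seed = 31)
  s1 <- run_aux_scan(sim$counts, om, standardize_covariate(raw),
                     pool_sizes = 30, settings = mcmc_settings_desk(),
                     seed = 32)
  s2 <- run_aux_scan(sim$counts, om, standardize_covariate(5 * raw - 2),
                     pool_sizes = 30, settings = mcmc_settings_desk(),
                     seed = 32)
  expect_identical(tidy(s1)$bf_db, tidy(s2)$bf_db)
})

test_that("posterior effect sizes track per-SNP regression slopes", {
  # with independent populations the model reduces to per-SNP regression
  # of frequency on covariate; beta_hat of confidently included SNPs
  # should correlate strongly with OLS slopes on the latent frequencies
  J <- 20
  om <- omega_identity(J, 0.1)
  cfg <- sim_config(n_pops = J, n_snps = 400, n_assoc = 200,
                    beta_effect = 0.12, omega_spec = om, maf_floor = 0.2,
                    coverage = 80, pool_sizes = 60)
  z <- as.numeric(scale(rnorm(J)))
  sim <- simulate_dataset(cfg, z, seed = 41)
  scan <- run_aux_scan(sim$counts, om, z, pool_sizes = 60,
                       settings = mcmc_settings(4, 100, 600, 500, 2),
                       seed = 42)
  res <- tidy(scan)
  ols <- apply(sim$freq_latent, 1, function(f) coef(lm(f ~ z))[2])
  sel <- res$pip > 0.5
  expect_gt(sum(sel), 20)
  expect_gt(cor(res$beta[sel], ols[sel]), 0.9)
})

test_that("merge_scan_outputs restores genome order and guards overlap", {
  sim <- simulate_dataset(sim_config(n_pops = 5, n_snps = 60, n_assoc = 0,
                                     omega_spec = omega_identity(5, 0.15)),
                          seed = 51)
  om <- omega_identity(5, 0.15)
  z <- as.numeric(scale(rnorm(5)))
  subs <- subsample_snps(sim$counts, 2)
  scans <- lapply(seq_along(subs), function(k) {
    run_aux_scan(subs[[k]], om, z, pool_sizes = 30,
                 settings = mcmc_settings(1, 20, 30, 20, 1), seed = k)
  })
  merged <- merge_scan_outputs(scans)
  expect_equal(tidy(merged)$pos, sim$counts$snps$pos)
  expect_identical(merge_scan_outputs(scans[1]), scans[[1]])
  expect_error(merge_scan_outputs(list(scans[[1]], scans[[1]])),
               "overlapping")
})
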