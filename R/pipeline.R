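#' Deterministic per-stage seed spawning
#'
#' One root seed deterministically spawns a stream of stage seeds (kept
#' below 2^31), so every stage of a pipeline run is independently
#' reproducible.
#'
#' @param root_seed Integer root seed.
#' @param n Number of seeds to spawn.
#' @return Integer vector of length `n`.
#' @export
spawn_seeds <- function(root_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(root_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Pipeline configuration
#'
#' Aggregates every stage's parameters: simulation design, filter
#' thresholds, MCMC schedule, the 0.5% tail fraction, the number of
#' circular permutations, and the region rule (top k = 50 SNPs per
#' covariate, at least 3 SNPs separated by less than 10 kb). Round-trips
#' through YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param sim A [sim_config()].
#' @param filter A [filter_params()].
#' @param mcmc An [mcmc_settings()].
#' @param tail_fraction Upper-tail fraction for enrichment (default
#'   0.005).
#' @param n_permutations Circular permutations (default 10000).
#' @param region_k,region_min_snps,region_max_gap_bp Region rule.
#' @param covariate_rho Target covariate-PC1 correlation for the
#'   simulated covariate.
#' @param seed Root seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), filter = filter_params(),
                            mcmc = mcmc_settings(),
                            tail_fraction = 0.005, n_permutations = 10000,
                            region_k = 50, region_min_snps = 3,
                            region_max_gap_bp = 10000,
                            covariate_rho = 0, seed = 1) {
  structure(list(sim = sim, filter = filter, mcmc = mcmc,
                 tail_fraction = tail_fraction,
                 n_permutations = n_permutations,
                 region_k = region_k, region_min_snps = region_min_snps,
                 region_max_gap_bp = region_max_gap_bp,
                 covariate_rho = covariate_rho, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$sim <- unclass(lst$sim)
  lst$sim$omega_spec <- as.vector(lst$sim$omega_spec)
  lst$filter <- unclass(lst$filter)
  lst$mcmc <- unclass(lst$mcmc)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  J <- lst$sim$n_pops
  om <- matrix(unlist(lst$sim$omega_spec), J, J)
  sim <- sim_config(n_pops = J, n_snps = lst$sim$n_snps,
                    n_assoc = lst$sim$n_assoc,
                    beta_effect = lst$sim$beta_effect,
                    beta_shape_a = lst$sim$beta_shape_a,
                    beta_shape_b = lst$sim$beta_shape_b,
                    maf_floor = lst$sim$maf_floor, omega_spec = om,
                    pool_sizes = unlist(lst$sim$pool_sizes),
                    coverage = unlist(lst$sim$coverage))
  pipeline_config(
    sim = sim,
    filter = do.call(filter_params, lst$filter),
    mcmc = do.call(mcmc_settings, lst$mcmc),
    tail_fraction = lst$tail_fraction,
    n_permutations = lst$n_permutations,
    region_k = lst$region_k, region_min_snps = lst$region_min_snps,
    region_max_gap_bp = lst$region_max_gap_bp,
    covariate_rho = lst$covariate_rho, seed = lst$seed)
}

#' Run the full desk-scale pipeline
#'
#' Chains simulate -> filter -> core model (Omega, XtX) -> AUX scan ->
#' enrichment -> candidate regions, writing every stage's output plus a
#' manifest (seeds, dimensions, checksums) into `out_dir`. Re-running
#' with the same configuration reproduces the checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return A list of stage results (invisibly also written to disk):
#'   `sim`, `filter_report`, `core`, `scan`, `enrichment`, `regions`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("poolgea_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(config$seed, 6)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  z <- stage("covariate", simulate_pc_correlated_covariate(
    config$sim$omega_spec, config$covariate_rho, seed = seeds[1]))
  sim <- stage("simulate", simulate_dataset(config$sim, as.numeric(z),
                                            seed = seeds[2]))
  write_pool_counts(sim$counts, file.path(out_dir, "counts.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  filt <- stage("filter", apply_filter_cascade(sim$counts, config$filter))
  utils::write.table(filt$report, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  core <- stage("omega", estimate_core_model(
    filt$counts, pool_sizes = config$sim$pool_sizes,
    settings = config$mcmc, seed = seeds[3]))
  om <- core$omega$omega
  colnames(om) <- filt$counts$pop_ids
  utils::write.table(om, file.path(out_dir, "omega.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  scan <- stage("scan", run_aux_scan(
    filt$counts, core$omega, as.numeric(z),
    pool_sizes = config$sim$pool_sizes,
    settings = config$mcmc, seed = seeds[4], xtx = core$xtx))
  write_scan_results(tidy(scan), file.path(out_dir, "scan.tsv"))

  res <- tidy(scan)
  top_bf <- upper_tail(res$bf_db, config$tail_fraction, res$snp_id)
  top_xtx <- upper_tail(res$xtx, config$tail_fraction, res$snp_id)
  fe <- stage("enrich", {
    row <- fold_enrichment_xtx(top_bf, top_xtx, nrow(res), "simulated")
    if (!is.na(row$fold_enrichment) && length(top_bf) > 0) {
      set.seed(seeds[5])
      pt <- circular_permutation_test(
        row$fold_enrichment, res$snp_id %in% top_bf,
        res$snp_id %in% top_xtx,
        n_perm = min(config$n_permutations, nrow(res) - 1))
      row$p_perm <- pt$p_perm
    } else row$p_perm <- NA_real_
    row
  })
  utils::write.table(fe, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  regions <- stage("regions", call_regions(
    select_top_snps(scan, min(config$region_k, nrow(res))),
    min_snps = config$region_min_snps,
    max_gap_bp = config$region_max_gap_bp, covariate = "simulated"))
  reg_flat <- dplyr::mutate(regions,
                            snp_ids = purrr::map_chr(.data$snp_ids, paste, collapse = ","),
                            covariates = purrr::map_chr(.data$covariates, paste, collapse = ","))
  utils::write.table(reg_flat, file.path(out_dir, "regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  files <- c("counts.tsv", "truth.tsv", "filter_report.tsv", "omega.tsv",
             "scan.tsv", "enrichment.tsv", "regions.tsv")
  manifest <- tibble(
    file = files,
    checksum = vapply(file.path(out_dir, files), digest::digest,
                      "", file = TRUE, USE.NAMES = FALSE),
    seed_root = config$seed)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(sim = sim, filter_report = filt$report, core = core,
                 scan = scan, enrichment = fe, regions = regions,
                 manifest = manifest, out_dir = out_dir))
}
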