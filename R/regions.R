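#' Select the top-k SNPs of a scan
#'
#' The k SNPs with the highest Bayes factor; ties are broken by genome
#' order.
#'
#' @param scan An `aux_scan` or its [tidy()] tibble.
#' @param k Number of SNPs to keep.
#' @param statistic Column ranked (default `bf_db`).
#' @return A tibble of the selected SNPs in genome order.
#' @export
select_top_snps <- function(scan, k, statistic = "bf_db") {
  df <- if (inherits(scan, "aux_scan")) tidy(scan) else as_tibble(scan)
  stopifnot(k >= 1, k <= nrow(df))
  ord <- order(-df[[statistic]], seq_len(nrow(df)))
  dplyr::arrange(df[ord[seq_len(k)], ],
                 match(.data$chrom, unique(df$chrom)), .data$pos)
}

#' Call candidate regions from top SNPs
#'
#' A candidate region is a maximal run of top SNPs on one chromosome in
#' which successive SNPs are separated by strictly less than `max_gap_bp`
#' base pairs, supported by at least `min_snps` SNPs. The region spans
#' the first to the last supporting SNP; its length is `end - start` bp.
#'
#' @param top Tibble of top SNPs with `chrom`, `pos`, `snp_id` (e.g. from
#'   [select_top_snps()]).
#' @param min_snps Minimum supporting SNPs per region (default 3).
#' @param max_gap_bp Strict gap bound between successive SNPs (default
#'   10000).
#' @param covariate Label carried into the result.
#' @return A tibble of regions: `chrom`, `start`, `end`, `n_snps`,
#'   `length_bp`, `snp_ids` (list column), `covariates` (list column).
#' @examples
#' top <- tibble::tibble(chrom = "chr1",
#'                       pos = c(1000, 4000, 9000, 25000, 32000, 41000, 48000))
#' top$snp_id <- paste0("s", seq_len(7))
#' call_regions(top)
#' @export
call_regions <- function(top, min_snps = 3, max_gap_bp = 10000,
                         covariate = NA_character_) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_snps = integer(), length_bp = integer(),
                  snp_ids = list(), covariates = list())
  if (!nrow(top)) return(empty)
  top <- dplyr::arrange(top, match(.data$chrom, unique(.data$chrom)), .data$pos)
  runs <- top |>
    group_by(.data$chrom) |>
    mutate(gap = .data$pos - lag(.data$pos),
           new_run = is.na(.data$gap) | .data$gap >= max_gap_bp,
           run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              n_snps = n(), snp_ids = list(.data$snp_id), .groups = "drop")
  runs <- runs[runs$n_snps >= min_snps, ]
  if (!nrow(runs)) return(empty)
  tibble(chrom = runs$chrom, start = as.integer(runs$start),
         end = as.integer(runs$end), n_snps = as.integer(runs$n_snps),
         length_bp = as.integer(runs$end - runs$start),
         snp_ids = runs$snp_ids,
         covariates = rep(list(covariate), nrow(runs)))
}

#' Merge candidate regions across covariates
#'
#' Regions from different covariates that overlap by at least one base
#' pair are reported once, with the union span, the union of supporting
#' SNPs and the list of covariates that detected them.
#'
#' @param regions A regions tibble (rows from several [call_regions()]
#'   calls bound together).
#' @return A merged regions tibble with a `shared` flag (detected by more
#'   than one covariate).
#' @export
merge_regions_across_variables <- function(regions) {
  if (!nrow(regions)) return(dplyr::mutate(regions, shared = logical(0)))
  regions <- dplyr::arrange(regions, match(.data$chrom, unique(.data$chrom)),
                            .data$start, .data$end)
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    cur$covariates <- list(sort(unique(unlist(cur$covariates))))
    cur$snp_ids <- list(sort(unique(unlist(cur$snp_ids))))
    cur$n_snps <- lengths(cur$snp_ids)
    cur$length_bp <- cur$end - cur$start
    cur$shared <- lengths(cur$covariates) > 1
    cur
  }
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!is.null(cur) && r$chrom == cur$chrom && r$start <= cur$end) {
      cur$end <- max(cur$end, r$end)
      cur$snp_ids <- list(c(unlist(cur$snp_ids), unlist(r$snp_ids)))
      cur$covariates <- list(c(unlist(cur$covariates), unlist(r$covariates)))
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- flush(cur)
      cur <- r
    }
  }
  out[[length(out) + 1]] <- flush(cur)
  dplyr::bind_rows(out)
}

#' Annotate regions with overlapping genes
#'
#' A gene is listed for a region iff its 1-based inclusive interval
#' intersects the region's interval on the same chromosome (touching at
#' one base pair counts; adjacency at +1 does not).
#'
#' @param regions A regions tibble.
#' @param genes Gene models tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return `regions` with `gene_ids` (list column) and `n_genes`.
#' @export
annotate_regions <- function(regions, genes) {
  if (nrow(regions) && nrow(genes) &&
      !any(regions$chrom %in% genes$chrom)) {
    warn("no shared chromosome names between regions and genes")
  }
  regions$gene_ids <- purrr::pmap(
    list(regions$chrom, regions$start, regions$end),
    function(ch, s, e) {
      hit <- genes$chrom == ch & genes$start <= e & genes$end >= s
      genes$gene_id[hit]
    })
  regions$n_genes <- lengths(regions$gene_ids)
  regions
}
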