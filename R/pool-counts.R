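#' Pool-Seq allele read-count container
#'
#' `pool_counts()` bundles per-SNP, per-population reference and alternate
#' allele read counts together with genomic coordinates. It is the central
#' observable of the package: every downstream stage (filtering, covariance
#' estimation, association scans) consumes it. SNPs are kept sorted by
#' chromosome (in a declared chromosome order) and position.
#'
#' The reference allele is the counted allele throughout: the population
#' allele frequency of a SNP is `ref / (ref + alt)`, and cells with zero
#' coverage are treated as missing rather than as frequency 0.
#'
#' @param snps A data frame with columns `chrom`, `pos` (1-based) and
#'   optionally `snp_id` (generated as `chrom_pos` when absent).
#' @param ref,alt Integer matrices, SNP x population, of reference and
#'   alternate allele read counts.
#' @param pop_ids Character vector of population identifiers, one per column.
#' @param chrom_order Chromosome ordering used for genome sorting. Defaults
#'   to the order of first appearance in `snps`.
#' @return An object of class `pool_counts`.
#' @examples
#' x <- pool_counts(
#'   data.frame(chrom = "1", pos = c(100, 200)),
#'   ref = matrix(c(10, 5, 12, 0), 2), alt = matrix(c(2, 7, 0, 9), 2),
#'   pop_ids = c("A", "B")
#' )
#' coverage(x)
#' @export
pool_counts <- function(snps, ref, alt, pop_ids = NULL, chrom_order = NULL) {
  snps <- as_tibble(snps)
  if (!all(c("chrom", "pos") %in% names(snps))) {
    abort("`snps` must have columns `chrom` and `pos`")
  }
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  if (!identical(dim(ref), dim(alt))) abort("`ref` and `alt` dimensions differ")
  if (nrow(ref) != nrow(snps)) abort("count rows do not match `snps` rows")
  if (anyNA(ref) || anyNA(alt) || any(ref < 0) || any(alt < 0)) {
    abort("read counts must be non-negative integers without NA")
  }
  if (is.null(pop_ids)) pop_ids <- paste0("pop", seq_len(ncol(ref)))
  if (length(pop_ids) != ncol(ref)) abort("`pop_ids` length does not match count columns")
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (is.null(snps[["snp_id"]])) snps$snp_id <- paste(snps$chrom, snps$pos, sep = "_")
  if (is.null(chrom_order)) chrom_order <- unique(snps$chrom)
  if (!all(snps$chrom %in% chrom_order)) abort("`chrom_order` does not cover all chromosomes")
  x <- structure(
    list(snps = snps[c("chrom", "pos", "snp_id")], ref = unname(ref),
         alt = unname(alt), pop_ids = as.character(pop_ids),
         chrom_order = as.character(chrom_order)),
    class = "pool_counts"
  )
  x <- sort_pool_counts(x)
  key <- paste(x$snps$chrom, x$snps$pos)
  if (anyDuplicated(key)) abort("duplicate (chrom, pos) entries")
  x
}

#' Sort SNPs into genome order
#'
#' Orders SNPs by declared chromosome order, then position. Idempotent.
#' @param x A [pool_counts] object.
#' @return The object with rows in genome order.
#' @export
sort_pool_counts <- function(x) {
  ord <- order(match(x$snps$chrom, x$chrom_order), x$snps$pos)
  x$snps <- x$snps[ord, ]
  x$ref <- x$ref[ord, , drop = FALSE]
  x$alt <- x$alt[ord, , drop = FALSE]
  x
}

#' @export
print.pool_counts <- function(x, ...) {
  cat("<pool_counts> ", nrow(x$snps), " SNPs x ", length(x$pop_ids),
      " populations (", paste(x$chrom_order, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.pool_counts <- function(x) c(nrow(x$snps), length(x$pop_ids))

#' Per-cell read coverage
#' @param x A [pool_counts] object.
#' @return Integer matrix `ref + alt`, SNP x population.
#' @export
coverage <- function(x) x$ref + x$alt

#' Reference-allele frequencies from read counts
#'
#' @param x A [pool_counts] object.
#' @return Numeric matrix of `ref / coverage`; cells with zero coverage are
#'   `NA` (missing), never 0.
#' @export
allele_freq <- function(x) {
  cov <- coverage(x)
  f <- x$ref / cov
  f[cov == 0] <- NA_real_
  f
}

#' @export
as_tibble.pool_counts <- function(x, ...) {
  ref <- x$ref
  alt <- x$alt
  colnames(ref) <- paste0(x$pop_ids, "_ref")
  colnames(alt) <- paste0(x$pop_ids, "_alt")
  wide <- dplyr::bind_cols(x$snps, as_tibble(ref), as_tibble(alt))
  wide[, c("chrom", "pos", "snp_id",
           as.vector(rbind(paste0(x$pop_ids, "_ref"), paste0(x$pop_ids, "_alt"))))]
}

#' @export
tidy.pool_counts <- function(x, ...) {
  tibble(
    chrom = rep(x$snps$chrom, times = length(x$pop_ids)),
    pos = rep(x$snps$pos, times = length(x$pop_ids)),
    snp_id = rep(x$snps$snp_id, times = length(x$pop_ids)),
    pop_id = rep(x$pop_ids, each = nrow(x$snps)),
    ref = as.vector(x$ref),
    alt = as.vector(x$alt)
  )
}

#' Subset a pool_counts object by SNP index
#' @param x A [pool_counts] object.
#' @param i Integer or logical index over SNPs (genome order preserved).
#' @return A [pool_counts] object with the selected SNPs.
#' @export
slice_snps <- function(x, i) {
  x$snps <- x$snps[i, ]
  x$ref <- x$ref[i, , drop = FALSE]
  x$alt <- x$alt[i, , drop = FALSE]
  x
}

#' Interleaved SNP sub-sampling
#'
#' Divides a dataset into `n_subsets` interleaved sub-datasets: subset k
#' holds the SNPs at genome-order indices k, k + n, k + 2n, ... The subsets
#' partition the input, each spanning the whole genome, which is what makes
#' per-subset covariance estimates comparable.
#'
#' @param x A [pool_counts] object in genome order.
#' @param n_subsets Number of interleaved subsets (>= 1).
#' @return A list of `n_subsets` [pool_counts] objects.
#' @export
subsample_snps <- function(x, n_subsets) {
  n <- nrow(x$snps)
  if (n_subsets < 1) abort("`n_subsets` must be >= 1")
  if (n_subsets > n) abort("`n_subsets` exceeds the number of SNPs")
  lapply(seq_len(n_subsets), function(k) slice_snps(x, seq(k, n, by = n_subsets)))
}

#' Population metadata table
#'
#' Validates a population table: identifiers, haploid pool sizes (2 x the
#' number of diploid plants pooled) and optional coordinates.
#'
#' @param pop_id Character identifiers.
#' @param haploid_pool_size Integer haploid pool sizes (>= 2).
#' @param latitude,longitude Optional decimal-degree coordinates.
#' @return A tibble of class `population_set`.
#' @export
population_set <- function(pop_id, haploid_pool_size,
                           latitude = NULL, longitude = NULL) {
  haploid_pool_size <- as.integer(haploid_pool_size)
  if (any(haploid_pool_size < 2)) abort("haploid pool sizes must be >= 2")
  out <- tibble(pop_id = as.character(pop_id),
                haploid_pool_size = haploid_pool_size)
  if (!is.null(latitude)) out$latitude <- as.numeric(latitude)
  if (!is.null(longitude)) out$longitude <- as.numeric(longitude)
  class(out) <- c("population_set", class(out))
  out
}
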