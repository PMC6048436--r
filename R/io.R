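#' Read a Pool-Seq allele count file
#'
#' Two dialects are supported. `"tsv"`: a header line with columns `chrom`,
#' `pos`, `snp_id`, then `<pop>_ref`, `<pop>_alt` per population.
#' `"genobaypass"`: the BayPass layout — one line per SNP, space-separated
#' ref/alt count pairs in population order, no header and no coordinates
#' (SNPs are placed on a single pseudo-chromosome at consecutive positions
#' unless `snps` supplies coordinates).
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"genobaypass"`.
#' @param pop_ids Population identifiers; required for `"genobaypass"`
#'   unless `n_pops` is given (then `pop1..popJ` are generated).
#' @param n_pops Number of populations (genobaypass dialect).
#' @param snps Optional coordinate data frame (`chrom`, `pos`, optional
#'   `snp_id`) for the genobaypass dialect.
#' @param chrom_order Declared chromosome order (see [pool_counts]).
#' @return A [pool_counts] object; SNP order is taken from the file.
#' @export
read_pool_counts <- function(path, dialect = c("tsv", "genobaypass"),
                             pop_ids = NULL, n_pops = NULL, snps = NULL,
                             chrom_order = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
    need <- c("chrom", "pos", "snp_id")
    if (!all(need %in% names(tab))) abort("TSV dialect requires chrom, pos, snp_id columns")
    cnt_cols <- setdiff(names(tab), need)
    refs <- grep("_ref$", cnt_cols, value = TRUE)
    pops <- sub("_ref$", "", refs)
    alts <- paste0(pops, "_alt")
    if (!all(alts %in% cnt_cols) || length(c(refs, alts)) != length(cnt_cols)) {
      abort("TSV dialect requires paired <pop>_ref / <pop>_alt columns")
    }
    ref <- parse_count_matrix(tab[refs], path)
    alt <- parse_count_matrix(tab[alts], path)
    pool_counts(tab[need], ref, alt, pop_ids = pops, chrom_order = chrom_order)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    if (is.null(pop_ids)) {
      if (is.null(n_pops)) abort("genobaypass dialect needs `pop_ids` or `n_pops`")
      pop_ids <- paste0("pop", seq_len(n_pops))
    }
    J <- length(pop_ids)
    bad <- which(lengths(toks) != 2L * J)
    if (length(bad)) {
      abort(paste0("malformed row at line ", bad[1], ": expected ", 2L * J,
                   " fields, found ", lengths(toks)[bad[1]]))
    }
    m <- matrix(suppressWarnings(as.integer(unlist(toks))),
                nrow = length(toks), byrow = TRUE)
    if (anyNA(m)) {
      bad <- which(apply(is.na(m), 1, any))[1]
      abort(paste0("malformed row at line ", bad, ": non-integer count"))
    }
    if (any(m < 0)) abort("negative read count")
    ref <- m[, 2L * seq_len(J) - 1L, drop = FALSE]
    alt <- m[, 2L * seq_len(J), drop = FALSE]
    if (is.null(snps)) {
      snps <- tibble(chrom = "1", pos = seq_len(nrow(m)))
    }
    pool_counts(snps, ref, alt, pop_ids = pop_ids, chrom_order = chrom_order)
  }
}

parse_count_matrix <- function(df, path) {
  m <- suppressWarnings(vapply(df, as.integer, integer(nrow(df))))
  m <- matrix(m, nrow = nrow(df))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    abort(paste0("malformed row at line ", bad + 1L, " of ", path))
  }
  if (any(m < 0)) abort("negative read count")
  m
}

#' Write a Pool-Seq allele count file
#'
#' Inverse of [read_pool_counts()]; round-trips losslessly.
#'
#' @param x A [pool_counts] object.
#' @param path Output path.
#' @param dialect `"tsv"` or `"genobaypass"`.
#' @return `path`, invisibly.
#' @export
write_pool_counts <- function(x, path, dialect = c("tsv", "genobaypass")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    utils::write.table(as_tibble(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    J <- length(x$pop_ids)
    m <- matrix(0L, nrow(x$ref), 2L * J)
    m[, 2L * seq_len(J) - 1L] <- x$ref
    m[, 2L * seq_len(J)] <- x$alt
    writeLines(apply(m, 1, paste, collapse = " "), path)
  }
  invisible(path)
}

#' Write / read an association scan results table
#'
#' TSV with columns `chrom`, `pos`, `snp_id`, `beta`, `bf_db`, `xtx`, `pip`.
#'
#' @param result A scan result tibble (see [run_aux_scan()]).
#' @param path Output path.
#' @return `path` invisibly, or the tibble for the reader.
#' @export
write_scan_results <- function(result, path) {
  cols <- c("chrom", "pos", "snp_id", "beta", "bf_db", "xtx", "pip")
  df <- as.data.frame(result)[, cols]
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(
    chrom = "character", pos = "integer", snp_id = "character",
    beta = "numeric", bf_db = "numeric", xtx = "numeric", pip = "numeric"))
  as_tibble(tab)
}

#' Read gene models from a GFF3 file
#'
#' Keeps features of type `gene` only. Coordinates are 1-based inclusive,
#' as in GFF3.
#'
#' @param path GFF3 file path.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path) {
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character())
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) NULL)
    if (is.null(gr) || length(gr) == 0) return(empty)
    df <- as.data.frame(gr)
    df <- df[df$type == "gene", , drop = FALSE]
    if (nrow(df) == 0) return(empty)
    ids <- df$ID
    if (is.null(ids) || anyNA(ids)) abort("gene feature without an ID attribute")
    return(tibble(
      gene_id = as.character(ids),
      chrom = as.character(df$seqnames),
      start = as.integer(df$start),
      end = as.integer(df$end),
      strand = as.character(df$strand)
    ))
  }
  # minimal fallback parser (gene features only)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 1L) == 9L]
  f <- f[vapply(f, function(z) z[3] == "gene", TRUE)]
  if (!length(f)) return(empty)
  ids <- vapply(f, function(z) {
    m <- regmatches(z[9], regexpr("(?:^|;)ID=[^;]+", z[9]))
    if (!length(m)) abort("gene feature without an ID attribute")
    sub("^;?ID=", "", m)
  }, "")
  tibble(
    gene_id = ids,
    chrom = vapply(f, `[`, "", 1),
    start = as.integer(vapply(f, `[`, "", 4)),
    end = as.integer(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 7)
  )
}
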