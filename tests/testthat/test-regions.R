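test_that("the gap-scan toy yields the two expected regions", {
  top <- tibble::tibble(
    chrom = "chr1",
    pos = c(1000L, 4000L, 9000L, 25000L, 32000L, 41000L, 48000L),
    snp_id = paste0("s", 1:7))
  reg <- call_regions(top)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start, c(1000L, 25000L))
  expect_equal(reg$end, c(9000L, 48000L))
  expect_equal(reg$n_snps, c(3L, 4L))
  expect_equal(reg$length_bp, c(8000L, 23000L))
  expect_equal(reg$snp_ids[[1]], c("s1", "s2", "s3"))

  # two SNPs only: below min_snps, no region
  expect_equal(nrow(call_regions(top[1:2, ])), 0L)
  # a gap of exactly 10 kb breaks a run (strict inequality)
  exact <- tibble::tibble(chrom = "chr1", pos = c(0L, 10000L, 20000L),
                          snp_id = paste0("e", 1:3))
  expect_equal(nrow(call_regions(exact)), 0L)
  just_under <- tibble::tibble(chrom = "chr1", pos = c(0L, 9999L, 19998L),
                               snp_id = paste0("u", 1:3))
  expect_equal(nrow(call_regions(just_under)), 1L)
})

test_that("region calling is order-independent and gap-monotone", {
  set.seed(5)
  top <- tibble::tibble(
    chrom = sample(c("1", "2"), 60, replace = TRUE),
    pos = sample.int(2e5, 60), snp_id = paste0("r", 1:60))
  a <- call_regions(top)
  b <- call_regions(top[sample.int(60), ])
  expect_equal(a, b)
  # raising the gap threshold merges or extends, never splits
  for (i in 1:10) {
    pos <- sort(sample.int(3e5, 40))
    t2 <- tibble::tibble(chrom = "1", pos = pos, snp_id = paste0("m", 1:40))
    gaps <- c(2000, 8000, 20000, 50000)
    regs <- lapply(gaps, function(g) call_regions(t2, max_gap_bp = g))
    n_reg <- vapply(regs, nrow, 1L)
    covered <- vapply(regs, function(r) sum(r$n_snps), 1L)
    expect_true(all(diff(covered) >= 0))
    # supporting SNPs always a subset of the input set
    for (r in regs) expect_true(all(unlist(r$snp_ids) %in% t2$snp_id))
  }
})

test_that("select_top_snps ranks by BF with genome-order ties", {
  scan <- tibble::tibble(chrom = "1", pos = 1:10 * 100L,
                         snp_id = letters[1:10],
                         bf_db = c(5, 9, 9, 1, 7, 3, 2, 8, 0, 4))
  expect_equal(select_top_snps(scan, 3)$snp_id, c("b", "c", "h"))
  expect_equal(nrow(select_top_snps(scan, 10)), 10L)
  expect_equal(select_top_snps(scan, 1)$snp_id, "b")
  ties <- dplyr::mutate(scan, bf_db = 1)
  expect_equal(select_top_snps(ties, 2)$snp_id, c("a", "b"))
})

test_that("regions merge across covariates with any overlap", {
  rA <- call_regions(tibble::tibble(chrom = "chr1",
                                    pos = c(100L, 2000L, 5000L),
                                    snp_id = paste0("a", 1:3)),
                     covariate = "A")
  rB <- call_regions(tibble::tibble(chrom = "chr1",
                                    pos = c(4500L, 7000L, 9000L),
                                    snp_id = paste0("b", 1:3)),
                     covariate = "B")
  merged <- merge_regions_across_variables(dplyr::bind_rows(rA, rB))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 9000L)
  expect_equal(merged$covariates[[1]], c("A", "B"))
  expect_true(merged$shared)

  # identical regions collapse to one record with both labels
  rB2 <- dplyr::mutate(rA, covariates = list("B"))
  m2 <- merge_regions_across_variables(dplyr::bind_rows(rA, rB2))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$covariates[[1]], c("A", "B"))

  # disjoint regions pass through
  rC <- call_regions(tibble::tibble(chrom = "chr2",
                                    pos = c(1L, 500L, 900L),
                                    snp_id = paste0("c", 1:3)),
                     covariate = "C")
  m3 <- merge_regions_across_variables(dplyr::bind_rows(rA, rC))
  expect_equal(nrow(m3), 2L)
  expect_false(any(m3$shared))
})

test_that("gene overlap uses 1-based inclusive intersection", {
  reg <- tibble::tibble(chrom = "chr1", start = 1000L, end = 9000L,
                        n_snps = 3L, length_bp = 8000L,
                        snp_ids = list("x"), covariates = list("A"))
  genes <- tibble::tibble(
    gene_id = c("inside", "partial", "touch_end", "adjacent", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr9"),
    start = c(2000L, 8500L, 9000L, 9001L, 2000L),
    end = c(3000L, 12000L, 12000L, 12000L, 3000L))
  ann <- annotate_regions(reg, genes)
  expect_setequal(ann$gene_ids[[1]], c("inside", "partial", "touch_end"))
  expect_equal(ann$n_genes, 3L)
  expect_warning(
    annotate_regions(reg, dplyr::mutate(genes, chrom = "chrZ")),
    "chromosome")
})
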