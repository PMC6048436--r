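# small programmatic fixtures shared across tests

toy_counts <- function() {
  pool_counts(
    data.frame(chrom = c("1", "1"), pos = c(100L, 200L),
               snp_id = c("s1", "s2")),
    ref = matrix(c(12L, 20L, 6L, 0L), 2),
    alt = matrix(c(8L, 5L, 12L, 0L), 2),
    pop_ids = c("A", "B")
  )
}

# deterministic Spearman rank correlation, independent of stats::cor
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Mann-Whitney normalization of the ROC AUC (independent oracle)
auc_mann_whitney <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

write_gff3_fixture <- function(path) {
  lines <- c(
    "##gff-version 3",
    "1\ttest\tgene\t100\t200\t.\t+\t.\tID=g1;Name=GENE1",
    "1\ttest\tmRNA\t100\t200\t.\t+\t.\tID=m1;Parent=g1",
    "1\ttest\tmRNA\t100\t180\t.\t+\t.\tID=m2;Parent=g1",
    "2\ttest\tgene\t500\t900\t.\t-\t.\tID=g2",
    "2\ttest\tmRNA\t500\t900\t.\t-\t.\tID=m3;Parent=g2",
    "2\ttest\tmRNA\t510\t890\t.\t-\t.\tID=m4;Parent=g2",
    "2\ttest\tmRNA\t520\t880\t.\t-\t.\tID=m5;Parent=g2",
    "3\ttest\tgene\t1000\t1500\t.\t+\t.\tID=g3"
  )
  writeLines(lines, path)
  path
}

make_filter_toy <- function() {
  # 6 SNPs x 10 populations engineered so each filter removes exactly one:
  # SNP1 zero coverage in 8 pops; SNP2 inflated coverage (mean rel cov 2);
  # SNP3 identical frequency everywhere (sd = 0); SNP4 depleted coverage
  # (mean rel cov 0.3); SNP5 fixed (freq exactly 0 or 1) in every pop but
  # with sd above the floor; SNP6 clean.
  J <- 10
  cov <- matrix(20L, 6, J)
  cov[1, 1:8] <- 0L
  cov[2, ] <- 40L
  cov[4, ] <- 6L
  f <- matrix(rep(seq(0.2, 0.65, length.out = J), each = 6), 6, J)
  f[3, ] <- 0.5
  f[5, ] <- c(rep(1, 9), 0)
  ref <- matrix(as.integer(round(cov * f)), 6, J)
  ref[1, 1:8] <- 0L
  alt <- cov - ref
  pool_counts(data.frame(chrom = "1", pos = 1:6 * 100L), ref, alt)
}
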