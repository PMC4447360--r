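make_panel <- function(ids, pos = seq_along(ids) * 100,
                       chrom = "chr1", maf = 0.2) {
  variant_panel(data.frame(snp_id = ids, chrom = chrom, pos = pos,
                           eur_maf = maf))
}

test_that("ld_table canonicalises pairs and validates r2", {
  ld <- ld_table(c("b", "c"), c("a", "a"), c(0.5, 0.2))
  expect_equal(ld$snp_a, c("a", "a"))
  expect_equal(ld$snp_b, c("b", "c"))
  expect_equal(ld_lookup(ld, "b", "a"), 0.5)
  expect_equal(ld_lookup(ld, "a", "b"), 0.5)
  expect_equal(ld_lookup(ld, "b", "c"), 0)  # absent pair reads as 0
  expect_error(ld_table("a", "b", 1.2), "\\[0, 1\\]")
  expect_error(ld_table("a", "a", 0.5), "self pairs")
  expect_error(ld_table(c("a", "b"), c("b", "a"), c(0.5, 0.6)),
               "conflicting")
  f <- withr::local_tempfile()
  write_ld_table(ld, f)
  expect_identical(
    as.data.frame(read_ld_table(f, source = "unspecified")),
    as.data.frame(ld))
})

test_that("merging r2 sources averages disagreements and is commutative", {
  a <- ld_table(c("s1", "s1"), c("s2", "s3"), c(0.4, 0.7), source = "x")
  b <- ld_table("s1", "s2", 0.6, source = "y")
  m <- merge_r2_sources(a, b)
  expect_equal(ld_lookup(m, "s1", "s2"), 0.5)  # mean of 0.4, 0.6
  expect_equal(ld_lookup(m, "s1", "s3"), 0.7)  # single-source pair
  expect_equal(ld_lookup(m, "s2", "s3"), 0)    # absent in both
  m2 <- merge_r2_sources(b, a)
  expect_identical(as.data.frame(m), as.data.frame(m2))
})

test_that("greedy LD pruning keeps the first SNP of each linked pair", {
  panel <- make_panel(c("A", "B", "C"))
  ld <- ld_table(c("A", "B", "A"), c("B", "C", "C"), c(0.5, 0.5, 0.1))
  kept <- ld_prune(panel, ld)
  expect_equal(kept$snp_id, c("A", "C"))
  # no pair above threshold: identity
  weak <- ld_table(c("A", "B"), c("B", "C"), c(0.2, 0.25))
  expect_equal(ld_prune(panel, weak)$snp_id, c("A", "B", "C"))
  # boundary: exactly 0.3 is kept (strict > removal)
  bnd <- ld_table("A", "B", 0.3)
  expect_equal(ld_prune(panel, bnd)$snp_id, c("A", "B", "C"))
  # unsorted input rejected
  df <- data.frame(snp_id = c("B", "A"), chrom = "chr1",
                   pos = c(200, 100), eur_maf = 0.2)
  expect_error(ld_prune(df, ld), "sorted")
})

test_that("pruning is idempotent and leaves no pair above threshold", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    panel <- make_panel(sprintf("s%03d", 1:n))
    i <- sample.int(n, 150, replace = TRUE)
    j <- sample.int(n, 150, replace = TRUE)
    ok <- i != j & !duplicated(paste(pmin(i, j), pmax(i, j)))
    ld <- ld_table(panel$snp_id[i[ok]], panel$snp_id[j[ok]],
                   runif(sum(ok)))
    kept <- ld_prune(panel, ld)
    # scan: all pairwise r2 among kept <= 0.3
    in_kept <- ld$snp_a %in% kept$snp_id & ld$snp_b %in% kept$snp_id
    expect_true(all(ld$r2[in_kept] <= 0.3))
    expect_identical(ld_prune(kept, ld)$snp_id, kept$snp_id)
  }
})

test_that("functional-SNP selection intersects mapped genes with targets", {
  fmap <- functional_snp_map(data.frame(
    snp_id = c("s1", "s1", "s2", "s3", "s4", "s5"),
    gene_id = c("g1", "g2", "g3", "g2", "g4", "g5")))
  expect_equal(select_functional_snps_of_targets(fmap, character()),
               character())
  expect_equal(select_functional_snps_of_targets(fmap, "g2"),
               c("s1", "s3"))
  expect_equal(select_functional_snps_of_targets(fmap, c("g2", "g4")),
               c("s1", "s3", "s4"))
})

test_that("one-sided KS statistic is the supremum of the CDF excess", {
  same <- ks_one_sided(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  sep <- ks_one_sided(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(sep$statistic, 1)
  wrong <- ks_one_sided(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3))
  expect_equal(wrong$statistic, 0)
  expect_equal(wrong$p, 1)
  expect_error(ks_one_sided(numeric(), 1:3 / 10), "non-empty")
  # D+ in [0, 1] and monotone as the target shifts toward 0
  set.seed(37)
  bg <- runif(200)
  tg <- runif(100)
  d <- vapply(c(1, 0.7, 0.4, 0.1), function(sc)
    ks_one_sided(tg * sc, bg)$statistic, numeric(1))
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diff(d) >= -1e-12))
})

test_that("low-P enrichment builds the Fisher/KS table from SNP sets", {
  # 10 SNPs, 4 targets; 3 low-P overall, 2 of them targets
  ids <- sprintf("s%02d", 1:10)
  p <- setNames(c(0.001, 0.005, 0.5, 0.6, 0.002, 0.7, 0.8, 0.9, 0.95,
                  0.99), ids)
  res <- low_p_enrichment(ids, ids[1:4], p)
  expect_equal(res$table$k, 2)
  expect_equal(res$table$n, 4)
  expect_equal(res$table$K, 3)
  expect_equal(res$table$N, 10)
  expect_equal(res$fold, (2 / 4) / (3 / 10), tolerance = 1e-12)
  expect_equal(res$fisher_p, enum_upper_tail(2, 4, 3, 10),
               tolerance = 1e-12)
  expect_true(res$ks_p >= 0 && res$ks_p <= 1)
  # target = all: fold exactly 1
  expect_equal(low_p_enrichment(ids, ids, p)$fold, 1)
  expect_error(low_p_enrichment(ids, c("nope"), p), "outside")
  # SNPs missing from the summary are dropped with a message
  expect_message(low_p_enrichment(c(ids, "extra"), ids[1:2], p),
                 "dropping 1")
})

test_that("Fisher rejection rate is near alpha under a global null", {
  set.seed(43)
  n_rep <- 600
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    ids <- sprintf("s%03d", 1:200)
    p <- setNames(runif(200), ids)
    tgt <- sample(ids, 50)
    rej[i] <- suppressMessages(
      low_p_enrichment(ids, tgt, p)$fisher_p) < 0.05
  }
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05)
  # discrete Fisher tails are conservative, so allow the lower side
  expect_lte(sum(rej), ci[2])
})
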