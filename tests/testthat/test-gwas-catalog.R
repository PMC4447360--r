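write_catalog_tsv <- function(df) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("catalog parsing dedupes, splits multi-gene fields and filters ancestry", {
  f <- write_catalog_tsv(data.frame(
    trait = c("traitX", "traitX", "traitY", "traitZ"),
    gene = c("geneA", "geneA", "geneB, geneC", "geneD"),
    ancestry = c("European", "European", "European", "non-European")))
  cat_ <- parse_gwas_catalog(f)
  expect_equal(cat_$traits$traitX, "geneA")
  expect_equal(cat_$traits$traitY, c("geneB", "geneC"))
  expect_false("traitZ" %in% catalog_traits(cat_))  # excluded
  cat_all <- parse_gwas_catalog(f, require_european = FALSE)
  expect_true("traitZ" %in% catalog_traits(cat_all))

  bad <- write_catalog_tsv(data.frame(trait = "t", gene = "g"))
  expect_error(parse_gwas_catalog(bad), "ancestry")
})

test_that("supplementary genes grow the trait and the pool", {
  f <- write_catalog_tsv(data.frame(
    trait = c("CAD", "other"), gene = c("g1", "g2"),
    ancestry = "European"))
  cat_ <- parse_gwas_catalog(f, extra_genes = list(CAD = "g9"))
  expect_setequal(cat_$traits$CAD, c("g1", "g9"))
  expect_equal(length(cat_$pool), 3L)  # pool grew by 1
})

test_that("trait enrichment reproduces published fold cells from a catalog", {
  # reconstruct count-level structure: pool of 8277 genes, 2094
  # targets, IBD trait with 85 target / 232 total genes
  pool <- sprintf("g%04d", 1:8277)
  targets <- pool[1:2094]
  traits <- list(
    IBD = c(pool[1:85], pool[2095:2241]),          # 85/232
    Platelet = c(pool[101:132], pool[3000:3042]),  # 32/75
    CAD = c(pool[201:249], pool[4000:4095]),       # 49/145
    all_gwas = pool)                    # makes the pool the full set
  cat_ <- trait_catalog(traits)
  expect_equal(round(trait_enrichment(targets, cat_, "IBD")$fold, 2),
               1.45)
  expect_equal(round(trait_enrichment(targets, cat_, "Platelet")$fold, 2),
               1.69)
  expect_equal(round(trait_enrichment(targets, cat_, "CAD")$fold, 2),
               1.34)
  expect_equal(trait_enrichment(pool[8000:8276], cat_, "IBD")$fold, 0)
  expect_error(trait_enrichment(targets, cat_, "nope"), "unknown trait")
})

test_that("permutation enrichment matches exhaustive enumeration on a small pool", {
  pool <- sprintf("g%02d", 1:10)
  targets <- pool[1:5]
  trait <- pool[c(1, 2, 6)]
  cat_ <- trait_catalog(list(tr = trait, rest = pool))
  p_obs <- trait_enrichment(targets, cat_, "tr")$fisher_p
  # enumeration oracle over all C(10,3) = 120 subsets
  combs <- combn(10, 3)
  p_all <- apply(combs, 2, function(ix) {
    k <- sum(ix <= 5)
    enum_upper_tail(k, 3, 5, 10)
  })
  exact <- mean(p_all < p_obs)
  res <- permutation_enrichment(targets, cat_, "tr",
                                permutation_spec(n_perms = 4000,
                                                 seed = 11))
  expect_lt(abs(res$perm_p - exact), 0.03)
})

test_that("permutation draws are bit-reproducible and size-matched", {
  set.seed(47)
  pool <- sprintf("g%03d", 1:400)
  cat_ <- trait_catalog(list(a = sample(pool, 60), b = sample(pool, 30),
                             filler = pool))
  targets <- sample(pool, 100)
  r1 <- permutation_enrichment(targets, cat_, "a",
                               permutation_spec(300, seed = 5))
  r2 <- permutation_enrichment(targets, cat_, "a",
                               permutation_spec(300, seed = 5))
  expect_identical(r1$perm_p, r2$perm_p)
  expect_identical(r1$extra$avg_perm_fold, r2$extra$avg_perm_fold)
  # matched sizes keep the mean permuted fold near 1
  expect_gt(r1$extra$avg_perm_fold, 0.9)
  expect_lt(r1$extra$avg_perm_fold, 1.1)
})

test_that("permutation P-values floor at the resolution of the test", {
  expect_equal(format_perm_p(0, 1000), "<1.0e-03")
  expect_equal(format_perm_p(0, 10000), "<1.0e-04")
  expect_equal(format_perm_p(0.014, 1000), "0.014")
})

test_that("combined significance requires both tests below alpha", {
  expect_true(combined_significance(0.014, 0.0209))
  expect_false(combined_significance(0.03, 0.51))
  expect_true(combined_significance(0.049, 0.049))   # strict boundary
  expect_false(combined_significance(0.05, 0.01))
  expect_true(is.na(combined_significance(NA, 0.01)))  # indeterminate
  expect_equal(combined_significance(c(0.01, 0.2), c(0.02, 0.01)),
               c(TRUE, FALSE))
})
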