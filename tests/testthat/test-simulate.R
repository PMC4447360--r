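small_cfg <- function(...) {
  sim_config(n_genes = 100, n_peaks = 80, n_snps = 600,
             n_traits = 6, genes_per_trait = c(10, 20),
             snps_per_trait = c(10, 20), seed = 5, ...)
}

test_that("the whole study is deterministic under the seed", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1$gwas, s2$gwas)
  expect_identical(as.data.frame(s1$variants), as.data.frame(s2$variants))
  expect_identical(as.data.frame(s1$ld_hapmap), as.data.frame(s2$ld_hapmap))
  expect_identical(s1$catalog$traits, s2$catalog$traits)
  expect_identical(s1$trait_snps, s2$trait_snps)
  # and written output is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("generated artifacts pass every reader's validation", {
  d <- withr::local_tempdir()
  write_simulation(simulate_study(small_cfg()), d)
  expect_no_warning({
    read_bed(file.path(d, "ab1.bed"))
    read_bed(file.path(d, "ab_shared.bed"))
    read_gene_annotation(file.path(d, "genes.tsv"))
    read_variant_panel(file.path(d, "variants.tsv"))
    read_ld_table(file.path(d, "ld_hapmap_ceu.tsv"))
    read_ld_table(file.path(d, "ld_kg_eur.tsv"))
    read_gwas_summary(file.path(d, "gwas.tsv"))
    read_functional_snp_map(file.path(d, "functional_snp_map.tsv"))
    parse_gwas_catalog(file.path(d, "catalog.tsv"))
  })
})

test_that("annotation and config validation reject impossible demands", {
  expect_error(sim_config(n_genes = 0), "counts")
  expect_error(sim_config(tss_fraction = 1.2), "ratios")
  expect_error(sim_config(chrom_length = 100, peak_length_mean = 200),
               "exceed")
  genes <- simulate_annotation(sim_config(n_chroms = 2, n_genes = 10,
                                          n_snps = 10))
  expect_equal(nrow(genes), 10L)
  expect_equal(length(unique(genes$chrom)), 2L)
})

test_that("peak placement follows the TSS fraction and target length", {
  cfg <- sim_config(n_genes = 200, n_peaks = 1500, tss_fraction = 1,
                    n_snps = 10, seed = 9)
  genes <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, genes)
  mid <- (pk$start + pk$end) / 2
  near <- vapply(seq_len(nrow(pk)), function(i) {
    tss <- genes$tss[genes$chrom == pk$chrom[i]]
    any(abs(tss - mid[i]) <= 1e5 + (pk$end[i] - pk$start[i]))
  }, logical(1))
  expect_true(all(near))
  expect_lt(abs(mean(pk$end - pk$start) - cfg$peak_length_mean) /
              cfg$peak_length_mean, 0.1)
})

test_that("LD is confined to blocks and sources straddle a common truth", {
  cfg <- small_cfg()
  vr <- simulate_variants_with_ld(cfg)
  blk <- vr$blocks$block[match(vr$ld_hapmap$snp_a, vr$blocks$snp_id)]
  blk2 <- vr$blocks$block[match(vr$ld_hapmap$snp_b, vr$blocks$snp_id)]
  expect_true(all(blk == blk2))  # no between-block pair
  expect_true(all(vr$ld_hapmap$r2 >= 0 & vr$ld_hapmap$r2 <= 1))
  merged <- merge_r2_sources(vr$ld_hapmap, vr$ld_kg)
  expect_true(all(merged$r2 >= 0 & merged$r2 <= 1))
  expect_true(all(abs(vr$ld_hapmap$r2 - vr$ld_kg$r2) <=
                    2 * cfg$ld_jitter + 1e-12))
  # zero jitter: both sources identical, merge equals either
  cfg0 <- small_cfg(ld_jitter = 0)
  vr0 <- simulate_variants_with_ld(cfg0)
  expect_identical(vr0$ld_hapmap$r2, vr0$ld_kg$r2)
  m0 <- merge_r2_sources(vr0$ld_hapmap, vr0$ld_kg)
  expect_equal(ld_lookup(m0, vr0$ld_hapmap$snp_a, vr0$ld_hapmap$snp_b),
               vr0$ld_hapmap$r2)
})

test_that("without a boost the low-P rate among target SNPs is background", {
  cfg <- sim_config(n_genes = 300, n_peaks = 100, n_snps = 20000,
                    n_traits = 2, seed = 21)
  genes <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, genes)
  vr <- simulate_variants_with_ld(cfg)
  gw <- simulate_gwas(cfg, pk, genes, vr$variants)
  tgt <- select_functional_snps_of_targets(gw$fmap, gw$targets)
  rate <- mean(gw$gwas[tgt] < 0.01)
  expect_lt(abs(rate - 0.01), 0.006)
})

test_that("raising the boost raises the recovered fold", {
  folds <- vapply(c(0, 0.1), function(w) {
    med <- vapply(1:3, function(s) {
      cfg <- sim_config(n_genes = 600, n_peaks = 100, n_snps = 10000,
                        n_traits = 2, low_p_boost = w, seed = 100 + s)
      genes <- simulate_annotation(cfg)
      pk <- simulate_peaks(cfg, genes)
      vr <- simulate_variants_with_ld(cfg)
      gw <- simulate_gwas(cfg, pk, genes, vr$variants)
      all_snps <- unique(gw$fmap$snp_id)
      tgt <- select_functional_snps_of_targets(gw$fmap, gw$targets)
      suppressMessages(low_p_enrichment(all_snps, tgt, gw$gwas))$fold
    }, numeric(1))
    median(med)
  }, numeric(1))
  expect_gt(folds[2], folds[1])
})

test_that("LD planting places trait SNPs in peak blocks at the set level", {
  cfg <- sim_config(n_genes = 200, n_peaks = 200,
                    peak_length_mean = 1000, n_snps = 5000,
                    ld_block_size = 20, n_traits = 5,
                    n_planted_traits = 1, ld_enrichment_r2 = 0.8,
                    seed = 33)
  st <- simulate_study(cfg)
  ld <- merge_r2_sources(st$ld_hapmap, st$ld_kg)
  peak_ids <- select_peak_variants(st$variants, st$shared)
  planted <- st$trait_snps$snp_id[st$trait_snps$trait ==
                                    st$planted_traits[1]]
  pr <- max_r2_statistic(peak_ids, planted, ld)
  expect_gt(pr$average, 0.6)  # planted pairs centred on 0.8
  # every planted SNP shares a block with a peak SNP
  pb <- st$blocks$block[st$blocks$snp_id %in% peak_ids]
  expect_true(all(st$blocks$block[match(planted, st$blocks$snp_id)]
                  %in% pb))
})
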