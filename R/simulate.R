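# Seeded synthetic-data generators.
#
# The generator works at the r2 summary level: variants are laid down
# in hard LD blocks and pairwise r2 is drawn per within-block pair,
# because the pipeline consumes only r2 tables (no haplotypes).  All
# randomness derives from the config seed through fixed per-stage
# offsets, so every artifact is byte-reproducible.

.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1))
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulation configuration
#'
#' Collects every tunable of the synthetic study.  Defaults give a
#' desk-scale study: a few chromosomes, several hundred genes and
#' peaks with ChIP-seq-like lengths (~500 bp), a blocked variant panel
#' and ~20 traits, with all planted effects off (a global null).
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes genes across all chromosomes.
#' @param n_peaks peaks per simulated antibody set.
#' @param peak_length_mean mean peak length in bp.
#' @param tss_fraction fraction of peaks placed within 100 kb of a TSS
#'   (mirrors the near-TSS concentration of real TF binding).
#' @param n_snps variant panel size.
#' @param ld_block_size SNPs per LD block; blocks are hard (between-
#'   block r2 absent) so pruning behaviour is exactly predictable.
#' @param within_block_r2 Beta shape pair for within-block pairwise r2.
#' @param ld_jitter half-width of the uniform jitter separating the two
#'   emitted r2 sources from their common truth.
#' @param monomorphic_fraction fraction of panel SNPs with
#'   `eur_maf = 0`.
#' @param n_traits number of catalog traits.
#' @param genes_per_trait integer range (min, max) of genes per trait.
#' @param snps_per_trait integer range (min, max) of SNPs per trait.
#' @param n_planted_traits how many traits carry the planted effects.
#' @param target_fraction_of_trait fraction of a planted trait's genes
#'   drawn from peak-assigned genes (gene-level effect; 0 = null).
#' @param low_p_boost mixture weight of the `Beta(a, 1)` small-P
#'   component among SNPs mapped to peak target genes (0 = null); see
#'   [boost_for_fold()] for calibrating it to a desired fold.
#' @param beta_a shape of the small-P Beta component.
#' @param ld_enrichment_r2 centre of the overridden peak-trait r2 for
#'   LD-planted traits (0 = null).
#' @param seed master seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 4L, chrom_length = 10e6,
                       n_genes = 400L, n_peaks = 300L,
                       peak_length_mean = 500, tss_fraction = 0.9,
                       n_snps = 8000L, ld_block_size = 10L,
                       within_block_r2 = c(1, 3), ld_jitter = 0.05,
                       monomorphic_fraction = 0.05,
                       n_traits = 20L, genes_per_trait = c(20L, 60L),
                       snps_per_trait = c(20L, 60L),
                       n_planted_traits = 0L,
                       target_fraction_of_trait = 0,
                       low_p_boost = 0, beta_a = 0.2,
                       ld_enrichment_r2 = 0, seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks),
              peak_length_mean = peak_length_mean,
              tss_fraction = tss_fraction, n_snps = as.integer(n_snps),
              ld_block_size = as.integer(ld_block_size),
              within_block_r2 = within_block_r2, ld_jitter = ld_jitter,
              monomorphic_fraction = monomorphic_fraction,
              n_traits = as.integer(n_traits),
              genes_per_trait = as.integer(genes_per_trait),
              snps_per_trait = as.integer(snps_per_trait),
              n_planted_traits = as.integer(n_planted_traits),
              target_fraction_of_trait = target_fraction_of_trait,
              low_p_boost = low_p_boost, beta_a = beta_a,
              ld_enrichment_r2 = ld_enrichment_r2,
              seed = as.integer(seed))
  counts <- c(cfg$n_chroms, cfg$n_genes, cfg$n_peaks, cfg$n_snps,
              cfg$ld_block_size, cfg$n_traits)
  if (any(counts < 1)) stop("all counts must be >= 1")
  ratios <- c(cfg$tss_fraction, cfg$monomorphic_fraction,
              cfg$target_fraction_of_trait, cfg$low_p_boost,
              cfg$ld_enrichment_r2)
  if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0, 1]")
  if (cfg$chrom_length <= cfg$peak_length_mean)
    stop("chrom_length must exceed peak_length_mean")
  structure(cfg, class = "sim_config")
}

.chrom_labels <- function(cfg) sprintf("chr%02d", seq_len(cfg$n_chroms))

# split n items across chromosomes as evenly as possible
.per_chrom <- function(n, n_chroms) {
  base <- n %/% n_chroms
  extra <- n %% n_chroms
  base + (seq_len(n_chroms) <= extra)
}

#' Simulate a gene annotation
#'
#' TSS positions uniform per chromosome, unique gene ids, random
#' strand; deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return A [gene_annotation()].
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.sub_seed(cfg$seed, 101))
  counts <- .per_chrom(cfg$n_genes, cfg$n_chroms)
  if (any(counts > cfg$chrom_length))
    stop("n_genes exceeds available positions")
  labels <- .chrom_labels(cfg)
  chrom <- rep(labels, counts)
  tss <- unlist(lapply(counts, function(k)
    sort(sample.int(cfg$chrom_length, k))))
  gene_annotation(data.frame(
    gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
    chrom = chrom, tss = tss,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE))
}

#' Simulate a ChIP-seq-like peak set
#'
#' A configured fraction of peaks is placed within 100 kb of a random
#' TSS, the remainder uniformly; lengths are geometric-like around
#' `peak_length_mean`; scores are Q-value-like uniforms (smaller is
#' better).
#'
#' @param cfg a [sim_config()].
#' @param genes a [gene_annotation()].
#' @param label peak-set label.
#' @param seed_offset stage offset so multiple antibody sets differ.
#' @return A [peak_set()] with genome build `"sim1"`.
#' @export
simulate_peaks <- function(cfg, genes, label = "Ab1",
                           seed_offset = 202) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.sub_seed(cfg$seed, seed_offset))
  n <- cfg$n_peaks
  lens <- rgeom(n, 1 / cfg$peak_length_mean) + 1
  near <- runif(n) < cfg$tss_fraction
  gi <- sample.int(nrow(genes), n, replace = TRUE)
  centre <- ifelse(near,
                   genes$tss[gi] + round(runif(n, -1e5, 1e5)),
                   round(runif(n, 0, cfg$chrom_length)))
  chrom <- ifelse(near, genes$chrom[gi],
                  sample(.chrom_labels(cfg), n, replace = TRUE))
  start <- pmin(pmax(0, centre - lens %/% 2),
                cfg$chrom_length - lens - 1)
  start <- pmax(0, start)
  peak_set(data.frame(chrom = chrom, start = start, end = start + lens,
                      name = sprintf("%s_peak_%05d", label, seq_len(n)),
                      score = runif(n), stringsAsFactors = FALSE),
           label = label, genome_build = "sim1")
}

#' Simulate a variant panel with block LD structure
#'
#' SNPs are laid down uniformly per chromosome and grouped into
#' consecutive blocks of `ld_block_size`; every within-block pair gets
#' an r2 drawn from the configured Beta distribution, between-block r2
#' is absent (read as 0).  Two LD tables are emitted as noisy copies
#' of the common truth (symmetric uniform jitter of half-width
#' `ld_jitter`, clamped to `[0, 1]`), mimicking two r2 sources that
#' mostly but not exactly agree.
#'
#' @param cfg a [sim_config()].
#' @return List with `variants` (a [variant_panel()]), `blocks` (data
#'   frame `snp_id`, `block`), and the two [ld_table()]s `ld_hapmap`
#'   (source `"hapmap_ceu"`) and `ld_kg` (source `"kg_eur"`).
#' @export
simulate_variants_with_ld <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.sub_seed(cfg$seed, 303))
  n <- cfg$n_snps
  counts <- .per_chrom(n, cfg$n_chroms)
  labels <- .chrom_labels(cfg)
  chrom <- rep(labels, counts)
  pos <- unlist(lapply(counts, function(k)
    sort(sample.int(cfg$chrom_length, k))))
  maf <- runif(n, 0.05, 0.5)
  mono <- sample.int(n, round(cfg$monomorphic_fraction * n))
  maf[mono] <- 0
  snp_id <- sprintf("snp_%06d", seq_len(n))
  variants <- variant_panel(data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos, eur_maf = maf,
    stringsAsFactors = FALSE))
  # consecutive blocks within each chromosome
  within <- unlist(lapply(counts, seq_len))
  chrom_idx <- rep(seq_len(cfg$n_chroms), counts)
  raw_block <- chrom_idx * (max(counts) + 1) +
    (within - 1) %/% cfg$ld_block_size
  block <- match(raw_block, unique(raw_block))
  blocks <- data.frame(snp_id = snp_id, block = block,
                       stringsAsFactors = FALSE)
  # all within-block pairs
  sizes <- rle(block)$lengths
  offs <- cumsum(c(0, sizes[-length(sizes)]))
  tpl <- lapply(sort(unique(sizes[sizes >= 2])),
                function(s) utils::combn(s, 2))
  names(tpl) <- as.character(sort(unique(sizes[sizes >= 2])))
  ii <- jj <- vector("list", length(sizes))
  for (b in seq_along(sizes)) {
    s <- sizes[b]
    if (s < 2) next
    cp <- tpl[[as.character(s)]]
    ii[[b]] <- cp[1L, ] + offs[b]
    jj[[b]] <- cp[2L, ] + offs[b]
  }
  ii <- unlist(ii); jj <- unlist(jj)
  npairs <- length(ii)
  truth <- rbeta(npairs, cfg$within_block_r2[1], cfg$within_block_r2[2])
  a <- .clamp01(truth + runif(npairs, -cfg$ld_jitter, cfg$ld_jitter))
  b <- .clamp01(truth + runif(npairs, -cfg$ld_jitter, cfg$ld_jitter))
  list(variants = variants, blocks = blocks,
       ld_hapmap = ld_table(snp_id[ii], snp_id[jj], a,
                            source = "hapmap_ceu"),
       ld_kg = ld_table(snp_id[ii], snp_id[jj], b, source = "kg_eur"))
}

#' Mixture weight needed for a desired low-P fold enrichment
#'
#' Solves for the `low_p_boost` mixture weight `w` such that SNPs
#' drawing from `(1 - w) Uniform + w Beta(a, 1)` show a `P < p_thresh`
#' rate equal to `fold` times the overall panel rate, when the boosted
#' SNPs make up a `target_share` fraction of the panel.
#'
#' @param fold desired fold enrichment of the boosted subset.
#' @param target_share fraction of panel SNPs that are boosted.
#' @param p_thresh low-P threshold (default 0.01).
#' @param beta_a Beta shape of the small-P component (default 0.2).
#' @return Mixture weight in `[0, 1]`.
#' @export
boost_for_fold <- function(fold, target_share, p_thresh = 0.01,
                           beta_a = 0.2) {
  if (fold * target_share >= 1)
    stop("requested fold unattainable at this target share")
  rate_t <- fold * (1 - target_share) * p_thresh /
    (1 - fold * target_share)
  q <- p_thresh^beta_a
  w <- (rate_t - p_thresh) / (q - p_thresh)
  if (w < 0 || w > 1)
    stop("requested fold outside the attainable range")
  w
}

# overwrite (or append) canonical pairs in an ld_table
.override_pairs <- function(ld, a, b, r2) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  lo <- lo[keep]; hi <- hi[keep]; r2 <- r2[keep]; key <- key[keep]
  tab_key <- paste(ld$snp_a, ld$snp_b, sep = "\r")
  hit <- match(key, tab_key)
  df <- as.data.frame(ld)
  df$r2[hit[!is.na(hit)]] <- r2[!is.na(hit)]
  if (any(is.na(hit)))
    df <- rbind(df, data.frame(snp_a = lo[is.na(hit)],
                               snp_b = hi[is.na(hit)],
                               r2 = r2[is.na(hit)],
                               stringsAsFactors = FALSE))
  ld_table(df$snp_a, df$snp_b, df$r2, source = ld_source(ld))
}

#' Simulate GWAS-side inputs with optional planted effects
#'
#' Builds the trait catalog, GWAS summary P-values, functional-SNP map
#' and per-trait SNP lists for a simulated study:
#'
#' * each SNP is mapped to its nearest gene within 50 kb (the
#'   functional map), with a random tissue label;
#' * each trait receives a gene set; for the first
#'   `n_planted_traits` traits, `target_fraction_of_trait` of the
#'   genes are drawn from peak-assigned target genes;
#' * GWAS P-values are Uniform(0, 1), except SNPs mapped to peak
#'   target genes which draw from the
#'   `(1 - w) Uniform + w Beta(a, 1)` mixture with `w = low_p_boost`;
#' * each trait receives a SNP list; for LD-planted traits
#'   (`ld_enrichment_r2 > 0`) the SNPs are drawn from LD blocks
#'   containing a peak SNP and their r2 to the block's peak SNPs is
#'   overridden with draws centred on `ld_enrichment_r2` in both r2
#'   sources.
#'
#' @param cfg a [sim_config()].
#' @param peaks a [peak_set()] (the consolidated set).
#' @param genes a [gene_annotation()].
#' @param variants a [variant_panel()].
#' @param ld_sources list of the two [ld_table()]s (required, and
#'   returned possibly modified, when `ld_enrichment_r2 > 0`).
#' @param blocks block membership data frame from
#'   [simulate_variants_with_ld()] (required for LD planting).
#' @return List with `catalog`, `gwas` (named vector), `fmap`,
#'   `trait_snps` (data frame `trait`, `snp_id`), `ld_sources`,
#'   `targets` (peak-assigned genes), `map` (the peak-gene map) and
#'   `planted_traits` (labels carrying planted effects).
#' @export
simulate_gwas <- function(cfg, peaks, genes, variants,
                          ld_sources = NULL, blocks = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.sub_seed(cfg$seed, 404))
  map <- assign_genes(peaks, genes, rule = "single_nearest",
                      max_dist = 50000)
  targets <- target_genes(map)

  # functional map: nearest gene within 50 kb of each SNP
  tissues <- c("adipose", "liver", "blood", "brain", "haec")
  fmap_rows <- lapply(split(seq_len(nrow(variants)), variants$chrom),
                      function(ix) {
    g <- genes[genes$chrom == variants$chrom[ix[1]], , drop = FALSE]
    if (!nrow(g)) return(NULL)
    g <- g[order(g$tss), , drop = FALSE]
    pos <- variants$pos[ix]
    right <- findInterval(pos, g$tss) + 1L
    left <- right - 1L
    d_left <- ifelse(left >= 1, abs(pos - g$tss[pmax(left, 1L)]), Inf)
    d_right <- ifelse(right <= nrow(g),
                      abs(g$tss[pmin(right, nrow(g))] - pos), Inf)
    pick <- ifelse(d_left <= d_right, pmax(left, 1L),
                   pmin(right, nrow(g)))
    dist <- pmin(d_left, d_right)
    ok <- is.finite(dist) & dist <= 50000
    if (!any(ok)) return(NULL)
    data.frame(snp_id = variants$snp_id[ix][ok],
               gene_id = g$gene_id[pick[ok]],
               stringsAsFactors = FALSE)
  })
  fmap_df <- do.call(rbind, fmap_rows)
  if (is.null(fmap_df) || !nrow(fmap_df))
    stop("no SNP maps to a gene; increase gene or SNP density")
  fmap_df$category <- sample(tissues, nrow(fmap_df), replace = TRUE)
  fmap <- functional_snp_map(fmap_df)

  # trait gene sets
  n_planted <- min(cfg$n_planted_traits, cfg$n_traits)
  trait_names <- sprintf("trait_%02d", seq_len(cfg$n_traits))
  sizes <- sample(seq(cfg$genes_per_trait[1], cfg$genes_per_trait[2]),
                  cfg$n_traits, replace = TRUE)
  gene_pool <- genes$gene_id
  target_pool <- intersect(gene_pool, targets)
  other_pool <- setdiff(gene_pool, targets)
  trait_sets <- vector("list", cfg$n_traits)
  for (i in seq_len(cfg$n_traits)) {
    if (i <= n_planted && cfg$target_fraction_of_trait > 0) {
      m <- round(cfg$target_fraction_of_trait * sizes[i])
      if (m > length(target_pool))
        stop("planted demand exceeds available peak-assigned genes")
      trait_sets[[i]] <- c(sample(target_pool, m),
                           sample(other_pool, sizes[i] - m))
    } else {
      trait_sets[[i]] <- sample(gene_pool, sizes[i])
    }
  }
  names(trait_sets) <- trait_names
  catalog <- trait_catalog(trait_sets)

  # GWAS P-values with the planted small-P mixture
  p <- setNames(runif(nrow(variants)), variants$snp_id)
  if (cfg$low_p_boost > 0) {
    boosted <- unique(fmap$snp_id[fmap$gene_id %in% targets])
    hit <- runif(length(boosted)) < cfg$low_p_boost
    p[boosted[hit]] <- rbeta(sum(hit), cfg$beta_a, 1)
  }
  p <- pmin(pmax(p, 1e-300), 1)

  # trait SNP lists
  poly <- variants$snp_id[!is.na(variants$eur_maf) &
                            variants$eur_maf > 0]
  snp_sizes <- sample(seq(cfg$snps_per_trait[1], cfg$snps_per_trait[2]),
                      cfg$n_traits, replace = TRUE)
  ld_plant <- cfg$ld_enrichment_r2 > 0 && n_planted > 0
  if (ld_plant) {
    if (is.null(ld_sources) || is.null(blocks))
      stop("LD planting requires 'ld_sources' and 'blocks'")
    peak_snps <- select_peak_variants(variants, peaks)
    peak_blocks <- unique(blocks$block[blocks$snp_id %in% peak_snps])
    cand <- blocks$snp_id[blocks$block %in% peak_blocks]
    cand <- setdiff(intersect(cand, poly), peak_snps)
    if (!length(cand))
      stop("no candidate SNPs share an LD block with a peak SNP")
  }
  trait_snp_list <- vector("list", cfg$n_traits)
  for (i in seq_len(cfg$n_traits)) {
    if (ld_plant && i <= n_planted) {
      sz <- min(snp_sizes[i], length(cand))
      chosen <- sample(cand, sz)
      # override peak-trait pair r2 in both sources, centred on the
      # planted level
      kappa <- 25
      sh1 <- cfg$ld_enrichment_r2 * kappa
      sh2 <- (1 - cfg$ld_enrichment_r2) * kappa
      pairs <- do.call(rbind, lapply(chosen, function(s) {
        blk <- blocks$block[match(s, blocks$snp_id)]
        pk <- intersect(blocks$snp_id[blocks$block == blk], peak_snps)
        if (!length(pk)) return(NULL)
        data.frame(a = s, b = pk, stringsAsFactors = FALSE)
      }))
      if (!is.null(pairs) && nrow(pairs)) {
        r2_new <- .clamp01(rbeta(nrow(pairs), sh1, sh2))
        ld_sources <- lapply(ld_sources, .override_pairs,
                             a = pairs$a, b = pairs$b, r2 = r2_new)
      }
      trait_snp_list[[i]] <- chosen
    } else {
      trait_snp_list[[i]] <- sample(poly, min(snp_sizes[i],
                                              length(poly)))
    }
  }
  trait_snps <- data.frame(
    trait = rep(trait_names, lengths(trait_snp_list)),
    snp_id = unlist(trait_snp_list), stringsAsFactors = FALSE)

  list(catalog = catalog, gwas = p, fmap = fmap,
       trait_snps = trait_snps, ld_sources = ld_sources,
       targets = targets, map = map,
       planted_traits = if (n_planted > 0)
         trait_names[seq_len(n_planted)] else character())
}

#' Simulate a complete study
#'
#' Runs every generator in order and returns all pipeline inputs: two
#' antibody-like peak sets (the second a perturbed subset of the
#' first, so their intersection is non-trivial), their consolidated
#' intersection, the gene annotation, the blocked variant panel with
#' two r2 sources, and the GWAS-side artifacts of [simulate_gwas()].
#'
#' @param cfg a [sim_config()].
#' @return Named list of all study artifacts plus `config`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- simulate_annotation(cfg)
  ab1 <- simulate_peaks(cfg, genes, label = "Ab1", seed_offset = 202)
  set.seed(.sub_seed(cfg$seed, 250))
  keep <- sort(sample.int(nrow(ab1), round(0.8 * nrow(ab1))))
  sub <- as.data.frame(ab1)[keep, , drop = FALSE]
  trim_l <- floor(runif(nrow(sub), 0, 0.2) * (sub$end - sub$start))
  trim_r <- floor(runif(nrow(sub), 0, 0.2) * (sub$end - sub$start))
  sub$start <- sub$start + trim_l
  sub$end <- pmax(sub$start + 1, sub$end - trim_r)
  sub$name <- sprintf("Ab2_peak_%05d", seq_len(nrow(sub)))
  ab2 <- peak_set(sub, label = "Ab2", genome_build = "sim1")
  shared <- intersect_peak_sets(ab1, ab2, label = "Ab_Shared")
  vr <- simulate_variants_with_ld(cfg)
  gw <- simulate_gwas(cfg, shared, genes, vr$variants,
                      ld_sources = list(hapmap = vr$ld_hapmap,
                                        kg = vr$ld_kg),
                      blocks = vr$blocks)
  ld_sources <- if (is.null(gw$ld_sources))
    list(hapmap = vr$ld_hapmap, kg = vr$ld_kg) else gw$ld_sources
  list(config = cfg, genes = genes, ab1 = ab1, ab2 = ab2,
       shared = shared, variants = vr$variants, blocks = vr$blocks,
       ld_hapmap = ld_sources[[1]], ld_kg = ld_sources[[2]],
       catalog = gw$catalog, gwas = gw$gwas, fmap = gw$fmap,
       trait_snps = gw$trait_snps, targets = gw$targets,
       map = gw$map, planted_traits = gw$planted_traits)
}

#' Write a simulated study to disk
#'
#' Emits every format the pipeline readers consume -- BED peak sets,
#' TSV annotation, variant panel, LD tables, GWAS summary, functional
#' map, catalog and trait-SNP lists -- plus a JSON manifest recording
#' the configuration and seed.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_bed(study$ab1, fp("ab1.bed"))
  write_bed(study$ab2, fp("ab2.bed"))
  write_bed(study$shared, fp("ab_shared.bed"))
  write_gene_annotation(study$genes, fp("genes.tsv"))
  write_variant_panel(study$variants, fp("variants.tsv"))
  write_ld_table(study$ld_hapmap, fp("ld_hapmap_ceu.tsv"))
  write_ld_table(study$ld_kg, fp("ld_kg_eur.tsv"))
  write_gwas_summary(study$gwas, fp("gwas.tsv"))
  write_functional_snp_map(study$fmap, fp("functional_snp_map.tsv"))
  cat_df <- data.frame(
    trait = rep(names(study$catalog$traits),
                lengths(study$catalog$traits)),
    gene = unlist(study$catalog$traits, use.names = FALSE),
    ancestry = "European", stringsAsFactors = FALSE)
  write.table(cat_df, fp("catalog.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$trait_snps, fp("trait_snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(study$config), fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
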