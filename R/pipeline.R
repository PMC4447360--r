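# Config-driven orchestration of the four analyses, emitting tables
# shaped like the study summaries: per-antibody peak/gene bookkeeping,
# per-tissue functional-SNP enrichment, per-trait gene-level
# permutation enrichment, and per-trait LD proximity.

#' Analysis configuration
#'
#' Houses the pipeline constants: the low-P threshold, the LD pruning
#' threshold, the peak-to-gene window, permutation counts for the
#' gene- and SNP-level tests, the per-test alpha and the combined
#' (two-test) cutoff `alpha_each^2`.
#'
#' @param p_thresh GWAS low-P threshold (default 0.01).
#' @param r2_prune LD pruning threshold (default 0.3).
#' @param gene_window peak-to-gene distance bound in bp (default
#'   50 kb).
#' @param n_perms_gene gene-level permutations (default 1000).
#' @param n_perms_ld SNP-level permutations (default 10,000).
#' @param alpha_each per-test significance level (default 0.05).
#' @param combined_alpha combined cutoff (default 0.0025).
#' @param seed master seed; per-trait substreams are derived from it
#'   and the trait label.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(p_thresh = 0.01, r2_prune = 0.3,
                            gene_window = 50000,
                            n_perms_gene = 1000L, n_perms_ld = 10000L,
                            alpha_each = 0.05, combined_alpha = 0.0025,
                            seed = 1L) {
  stopifnot(p_thresh > 0, p_thresh < 1, r2_prune >= 0, r2_prune <= 1,
            gene_window > 0, n_perms_gene >= 1, n_perms_ld >= 1,
            alpha_each > 0, alpha_each < 1)
  structure(list(p_thresh = p_thresh, r2_prune = r2_prune,
                 gene_window = gene_window,
                 n_perms_gene = as.integer(n_perms_gene),
                 n_perms_ld = as.integer(n_perms_ld),
                 alpha_each = alpha_each,
                 combined_alpha = combined_alpha,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the
#' [analysis_config()] defaults.
#'
#' @param path YAML file.
#' @return An [analysis_config()].
#' @export
load_analysis_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

# deterministic 32-bit hash of a label, for per-trait RNG substreams
.label_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consolidate two antibody peak sets and summarise
#'
#' Intersects the two peak sets under the containment/overlap rule,
#' assigns target genes to each input set and to the intersection, and
#' returns per-set summaries (peak count, mean length, target genes,
#' genes with >1 peak, peaks with >1 gene).
#'
#' @param ab1,ab2 [peak_set()] objects (or BED paths).
#' @param genes a [gene_annotation()] (or TSV path).
#' @param config an [analysis_config()].
#' @param out_dir optional output directory; when given, writes
#'   `ab_shared.bed` and `peak_summary.tsv`.
#' @return List with `shared` (the intersection [peak_set()]),
#'   `maps` (peak-gene maps per set) and `summary` (data frame).
#' @export
run_intersect <- function(ab1, ab2, genes,
                          config = analysis_config(),
                          out_dir = NULL) {
  if (is.character(ab1)) ab1 <- read_bed(ab1, label = "Ab1")
  if (is.character(ab2)) ab2 <- read_bed(ab2, label = "Ab2")
  if (is.character(genes)) genes <- read_gene_annotation(genes)
  shared <- intersect_peak_sets(ab1, ab2, label = "Ab_Shared")
  sets <- list(ab1, ab2, shared)
  maps <- lapply(sets, assign_genes, genes = genes,
                 rule = "single_nearest", max_dist = config$gene_window)
  summary <- do.call(rbind, Map(peak_summary, sets, maps))
  names(maps) <- summary$label
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_bed(shared, file.path(out_dir, "ab_shared.bed"))
    .write_tsv(summary, file.path(out_dir, "peak_summary.tsv"))
  }
  list(shared = shared, maps = maps, summary = summary)
}

#' Functional-SNP low-P enrichment per tissue/category
#'
#' LD-prunes the full variant panel once, then for each tissue or
#' annotation category of the functional map subsets to that
#' category's SNPs, selects those mapped to target genes, and runs
#' [low_p_enrichment()] (Fisher + one-sided KS).  A Bonferroni flag
#' marks categories passing `alpha_each / n_categories`.
#'
#' @param variants a [variant_panel()].
#' @param ld an [ld_table()] used for pruning.
#' @param gwas named vector from [gwas_summary()].
#' @param fmap a [functional_snp_map()] with a `category` column.
#' @param targets character vector of target genes.
#' @param config an [analysis_config()].
#' @param out_dir optional; writes `snp_enrichment.tsv`.
#' @return Data frame, one row per category: counts, fold, Fisher and
#'   KS P-values, Bonferroni flag, plus pruning bookkeeping.
#' @export
run_snp_enrichment <- function(variants, ld, gwas, fmap, targets,
                               config = analysis_config(),
                               out_dir = NULL) {
  pruned <- ld_prune(variants, ld, r2_max = config$r2_prune)
  message(sprintf("LD pruning: %d -> %d SNPs (r2 > %g removed)",
                  nrow(variants), nrow(pruned), config$r2_prune))
  panel <- intersect(pruned$snp_id, names(gwas))
  cats <- sort(unique(fmap$category))
  cats <- cats[!is.na(cats)]
  if (!length(cats)) cats <- NA_character_
  rows <- lapply(cats, function(cc) {
    sub <- if (is.na(cc)) fmap else fmap[fmap$category == cc, ,
                                         drop = FALSE]
    cat_snps <- intersect(unique(sub$snp_id), panel)
    tgt_snps <- intersect(select_functional_snps_of_targets(sub, targets),
                          cat_snps)
    if (!length(cat_snps)) return(NULL)
    res <- low_p_enrichment(cat_snps, tgt_snps, gwas,
                            p_thresh = config$p_thresh,
                            label = if (is.na(cc)) "all" else cc)
    as.data.frame(res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(label = character(), k = numeric(), n = numeric(),
                      K = numeric(), N = numeric(), fold = numeric(),
                      fisher_p = numeric(), ks_p = numeric(),
                      bonferroni_significant = logical())
  } else {
    out$perm_p <- NULL; out$n_perms <- NULL
    out$bonferroni_significant <-
      out$fisher_p < config$alpha_each / nrow(out)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .write_tsv(out, file.path(out_dir, "snp_enrichment.tsv"))
  }
  out
}

#' Gene-level trait enrichment with matched-size permutations
#'
#' For every trait in the catalog runs [trait_enrichment()] and
#' [permutation_enrichment()] against the pooled all-GWAS-gene
#' background, with an optional exclusion gene list (e.g. lipid genes)
#' removed from trait sets before testing.
#'
#' @param targets character vector of target genes.
#' @param catalog a [trait_catalog()].
#' @param config an [analysis_config()].
#' @param exclude optional character vector of genes removed from each
#'   trait set (the pool is left untouched).
#' @param out_dir optional; writes `gene_enrichment.tsv`.
#' @return Data frame, one row per trait, sorted by permutation
#'   P-value: counts, fold, mean permuted fold, Fisher P, permutation
#'   P with display form.
#' @export
run_gene_enrichment <- function(targets, catalog,
                                config = analysis_config(),
                                exclude = NULL, out_dir = NULL) {
  stopifnot(inherits(catalog, "trait_catalog"))
  if (!is.null(exclude)) {
    catalog <- trait_catalog(lapply(catalog$traits, setdiff,
                                    y = exclude))
  }
  rows <- lapply(catalog_traits(catalog), function(tr) {
    res <- permutation_enrichment(
      targets, catalog, tr,
      spec = permutation_spec(n_perms = config$n_perms_gene,
                              seed = .label_seed(config$seed, tr),
                              comparison = "strict_less"))
    df <- as.data.frame(res)
    df$avg_perm_fold <- res$extra$avg_perm_fold
    df$perm_p_display <- res$extra$perm_p_display
    df
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "label"] <- "trait"
  out$ks_p <- NULL
  out <- out[order(out$perm_p, out$fisher_p), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .write_tsv(out, file.path(out_dir, "gene_enrichment.tsv"))
  }
  out
}

#' SNP-level LD proximity analysis across traits
#'
#' For every trait with SNPs, prunes trait and peak SNPs, computes the
#' average-max-r2 pairing statistic and its trait-label permutation
#' P-value (see [run_trait_ld_report()]).  The null pool is the union
#' of all catalog trait SNPs.
#'
#' @param peaks consolidated [peak_set()].
#' @param variants a [variant_panel()].
#' @param trait_snps data frame `trait`, `snp_id`.
#' @param ld merged [ld_table()].
#' @param config an [analysis_config()].
#' @param out_dir optional; writes `ld_enrichment.tsv`.
#' @return Data frame, one row per trait, sorted by permutation P.
#' @export
run_ld_enrichment <- function(peaks, variants, trait_snps, ld,
                              config = analysis_config(),
                              out_dir = NULL) {
  peak_ids <- select_peak_variants(variants, peaks)
  peak_vars <- variants[variants$snp_id %in% peak_ids, , drop = FALSE]
  class(peak_vars) <- c("variant_panel", "data.frame")
  pool <- unique(trait_snps$snp_id)
  traits <- sort(unique(trait_snps$trait))
  rows <- lapply(traits, function(tr) {
    ids <- trait_snps$snp_id[trait_snps$trait == tr]
    tv <- variants[variants$snp_id %in% ids, , drop = FALSE]
    class(tv) <- c("variant_panel", "data.frame")
    run_trait_ld_report(tr, tv, peak_vars, ld, pool,
                        r2_prune = config$r2_prune,
                        n_perms = config$n_perms_ld,
                        seed = .label_seed(config$seed, tr))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out <- out[order(out$perm_p), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(out_dir) && !is.null(out)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .write_tsv(out, file.path(out_dir, "ld_enrichment.tsv"))
  }
  out
}

#' Combine the gene- and SNP-level permutation tests
#'
#' Joins the two per-trait result tables and flags traits passing
#' `alpha_each` in both permutation tests (combined cutoff
#' `alpha_each^2`).  Traits missing from either table are
#' indeterminate (`NA`), not non-significant.
#'
#' @param gene_results output of [run_gene_enrichment()].
#' @param ld_results output of [run_ld_enrichment()].
#' @param config an [analysis_config()].
#' @return Data frame `trait`, `gene_perm_p`, `ld_perm_p`,
#'   `combined_significant`.
#' @export
combine_trait_results <- function(gene_results, ld_results,
                                  config = analysis_config()) {
  traits <- union(gene_results$trait, ld_results$trait)
  gp <- gene_results$perm_p[match(traits, gene_results$trait)]
  sp <- ld_results$perm_p[match(traits, ld_results$trait)]
  data.frame(trait = traits, gene_perm_p = gp, ld_perm_p = sp,
             combined_significant =
               combined_significance(gp, sp, config$alpha_each),
             stringsAsFactors = FALSE)
}
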