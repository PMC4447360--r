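# SNP-level LD proximity analysis: peak-SNP selection, the
# average-max-r2 pairing statistic and its trait-label permutation
# null.

#' Select polymorphic variants inside peaks
#'
#' Peak SNPs are panel variants that are polymorphic in Europeans
#' (`eur_maf > 0`) and whose position falls inside a peak interval
#' (half-open containment: a SNP at the `end` coordinate is outside).
#'
#' @param panel a [variant_panel()] carrying `eur_maf`.
#' @param peaks a [peak_set()].
#' @return Character vector of SNP ids.
#' @export
select_peak_variants <- function(panel, peaks) {
  if (!nrow(panel) || !nrow(peaks)) return(character())
  poly <- !is.na(panel$eur_maf) & panel$eur_maf > 0
  snp_gr <- GenomicRanges::GRanges(
    seqnames = panel$chrom,
    ranges = IRanges::IRanges(start = panel$pos + 1, width = 1L))
  inside <- suppressWarnings(
    GenomicRanges::countOverlaps(snp_gr, .as_granges(peaks))) > 0
  sort(panel$snp_id[poly & inside])
}

#' Average-max-r2 pairing between peak SNPs and trait SNPs
#'
#' For each peak SNP with at least one recorded r2 against a trait
#' SNP, only the maximum of those r2 values enters the average, so
#' each peak SNP maps onto at most one trait SNP while a trait SNP may
#' serve as the best partner of several peak SNPs.  Peak SNPs with no
#' recorded pair contribute nothing (they are excluded from the
#' denominator, not zero-filled).
#'
#' @param peak_snps,trait_snps character vectors of SNP ids.
#' @param ld an [ld_table()].
#' @return Object of class `ld_pairing`: list with `pairs` (data frame
#'   `peak_snp`, `trait_snp`, `r2`), `contributing_count` and
#'   `average`.  Errors when no peak SNP has a recorded pair.
#' @export
max_r2_statistic <- function(peak_snps, trait_snps, ld) {
  edges <- .ld_edges(peak_snps, trait_snps, ld)
  if (!nrow(edges))
    stop("average-max-r2 undefined: no recorded r2 between peak and trait SNPs")
  ord <- order(-edges$r2, edges$trait_snp)
  edges <- edges[ord, , drop = FALSE]
  best <- edges[!duplicated(edges$peak_snp), , drop = FALSE]
  best <- best[order(best$peak_snp), , drop = FALSE]
  rownames(best) <- NULL
  structure(list(pairs = best,
                 contributing_count = nrow(best),
                 average = mean(best$r2)),
            class = "ld_pairing")
}

#' @export
print.ld_pairing <- function(x, ...) {
  cat(sprintf("ld_pairing: %d contributing peak SNPs, average max r2 = %.4f\n",
              x$contributing_count, x$average))
  invisible(x)
}

# LD rows connecting a peak SNP to a candidate SNP, oriented
# (peak_snp, trait_snp, r2).  SNP ids shared by both roles pair in
# both orientations.
.ld_edges <- function(peak_snps, cand_snps, ld) {
  pa <- ld$snp_a %in% peak_snps
  pb <- ld$snp_b %in% peak_snps
  ca <- ld$snp_a %in% cand_snps
  cb <- ld$snp_b %in% cand_snps
  fwd <- pa & cb
  rev <- pb & ca
  data.frame(
    peak_snp = c(ld$snp_a[fwd], ld$snp_b[rev]),
    trait_snp = c(ld$snp_b[fwd], ld$snp_a[rev]),
    r2 = c(ld$r2[fwd], ld$r2[rev]),
    stringsAsFactors = FALSE)
}

#' Trait-label permutation null for the average-max-r2 statistic
#'
#' Generates an empirical null by repeatedly drawing, without
#' replacement, a SNP set of the same size as the trait's from the
#' pooled catalog SNPs (equivalent to permuting trait labels
#' restricted to the tested trait) and recomputing the average-max-r2
#' statistic.  The permutation P-value is the proportion of null
#' averages greater than or equal to the true statistic; a zero count
#' is displayed as a floor (`P<1e-04` at 10,000 permutations).
#' Permutations in which no peak SNP has a recorded pair are dropped
#' from the denominator; if more than half are undefined the test
#' aborts with a diagnostic (the pool is too sparse in the LD table).
#'
#' @param true_stat observed average-max-r2 (see
#'   [max_r2_statistic()]).
#' @param peak_snps character vector of peak SNP ids.
#' @param pool character vector: the pooled catalog SNPs from which
#'   null sets are drawn.
#' @param n_trait number of SNPs per null set (the trait's SNP count).
#' @param ld an [ld_table()].
#' @param n_perms number of permutations (default 10,000).
#' @param seed integer RNG seed.
#' @return An [enrichment_result()] whose `extra` carries the null
#'   mean, the defined-permutation count and `perm_p_display`.
#' @export
trait_label_permutation_test <- function(true_stat, peak_snps, pool,
                                         n_trait, ld,
                                         n_perms = 10000L, seed = 1L) {
  pool <- unique(as.character(pool))
  P <- length(pool)
  if (n_trait > P) stop("trait SNP set larger than the pool")
  if (n_trait < 1) stop("trait SNP set is empty")
  edges <- .ld_edges(peak_snps, pool, ld)
  # pre-sorted by decreasing r2 so the first retained row per peak SNP
  # is its maximum within any pool subset
  ord <- order(-edges$r2)
  edges <- edges[ord, , drop = FALSE]
  pool_idx <- match(edges$trait_snp, pool)
  peak_f <- edges$peak_snp
  set.seed(as.integer(seed %% .Machine$integer.max))
  null_avg <- rep(NA_real_, n_perms)
  for (i in seq_len(n_perms)) {
    picked <- logical(P)
    picked[sample.int(P, n_trait)] <- TRUE
    sel <- picked[pool_idx]
    if (!any(sel)) next
    pk <- peak_f[sel]
    null_avg[i] <- mean(edges$r2[sel][!duplicated(pk)])
  }
  defined <- !is.na(null_avg)
  if (mean(defined) < 0.5)
    stop("LD permutation null undefined in >50% of permutations: ",
         "pool too sparse in the LD table")
  perm_p <- mean(null_avg[defined] >= true_stat)
  enrichment_result(
    perm_p = perm_p, n_perms = as.integer(n_perms),
    label = "ld_permutation",
    extra = list(null_mean = mean(null_avg[defined]),
                 n_defined = sum(defined),
                 true_stat = true_stat,
                 perm_p_display = format_perm_p(perm_p, n_perms)))
}

#' Per-trait LD proximity report
#'
#' Runs the full SNP-level pipeline for one trait: LD-prunes the trait
#' SNPs and the peak SNPs independently, computes the average-max-r2
#' pairing between the pruned sets, and assigns an empirical
#' permutation P-value by trait-label permutation.  Returns the
#' bookkeeping columns of the analysis: trait SNP count (pruned),
#' trait SNPs having a recorded r2 with a peak SNP, peak SNP counts
#' before and after pruning, the average and the P-value.
#'
#' @param trait trait label (for the report row).
#' @param trait_variants [variant_panel()] rows for the trait's SNPs.
#' @param peak_variants [variant_panel()] rows for the peak SNPs.
#' @param ld an [ld_table()] (typically [merge_r2_sources()] output).
#' @param pool character vector of pooled catalog SNPs for the null.
#' @param r2_prune pruning threshold (default 0.3).
#' @param n_perms permutations (default 10,000).
#' @param seed integer RNG seed.
#' @return One-row data frame, or `NULL` (with a warning) for a trait
#'   with no SNPs; a trait whose pruned SNPs share no recorded r2 with
#'   the peak SNPs yields `NA` statistics.
#' @export
run_trait_ld_report <- function(trait, trait_variants, peak_variants,
                                ld, pool, r2_prune = 0.3,
                                n_perms = 10000L, seed = 1L) {
  if (is.null(trait_variants) || !nrow(trait_variants)) {
    warning(sprintf("trait '%s' has no GWAS SNPs; skipped", trait))
    return(NULL)
  }
  trait_pruned <- ld_prune(trait_variants, ld, r2_max = r2_prune)
  peak_pruned <- ld_prune(peak_variants, ld, r2_max = r2_prune)
  peak_ids <- peak_pruned$snp_id
  trait_ids <- trait_pruned$snp_id
  edges <- .ld_edges(peak_ids, trait_ids, ld)
  n_with_ld <- length(unique(edges$trait_snp))
  if (!nrow(edges)) {
    warning(sprintf("trait '%s': no recorded r2 between pruned trait and peak SNPs",
                    trait))
    avg <- NA_real_
    perm <- list(perm_p = NA_real_,
                 extra = list(perm_p_display = NA_character_))
  } else {
    pairing <- max_r2_statistic(peak_ids, trait_ids, ld)
    avg <- pairing$average
    perm <- trait_label_permutation_test(
      avg, peak_ids, pool, n_trait = length(trait_ids), ld,
      n_perms = n_perms, seed = seed)
  }
  data.frame(trait = trait,
             avg_max_r2 = avg,
             n_gwas_snps = length(trait_ids),
             n_gwas_snps_with_ld = n_with_ld,
             n_peak_snps_before = nrow(peak_variants),
             n_peak_snps_after = nrow(peak_pruned),
             perm_p = perm$perm_p,
             perm_p_display = perm$extra$perm_p_display,
             stringsAsFactors = FALSE)
}
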