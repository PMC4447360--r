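# Functional-SNP enrichment of low GWAS P-values: LD pruning to
# independent SNPs, SNP-to-target-gene selection, and the Fisher +
# one-sided KS excess-of-small-P test.

#' Construct or read a variant panel
#'
#' A variant panel is a data frame with one row per SNP: `snp_id`
#' (unique), `chrom`, `pos` and optionally `eur_maf` (European minor
#' allele frequency in `[0, 0.5]`; 0 marks a monomorphic site).
#'
#' @param df data frame with the columns above.
#' @return Validated data frame of class `variant_panel`, sorted by
#'   (chrom, pos).
#' @export
variant_panel <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("snp_id", "chrom", "pos")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("variant columns missing: ", paste(missing_cols, collapse = ", "))
  out <- data.frame(snp_id = as.character(df$snp_id),
                    chrom = as.character(df$chrom),
                    pos = as.numeric(df$pos),
                    eur_maf = if ("eur_maf" %in% names(df))
                      as.numeric(df$eur_maf) else NA_real_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp_id)) stop("duplicate snp_id in panel")
  if (nrow(out) && any(out$pos < 0)) stop("pos must be >= 0")
  maf <- out$eur_maf[!is.na(out$eur_maf)]
  if (length(maf) && any(maf < 0 | maf > 0.5))
    stop("eur_maf must lie in [0, 0.5]")
  out <- out[order(out$chrom, out$pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_panel", "data.frame")
  out
}

#' @rdname variant_panel
#' @param path TSV with header `snp_id chrom pos [eur_maf]`.
#' @export
read_variant_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  variant_panel(read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE))
}

#' @rdname variant_panel
#' @param panel panel to write.
#' @export
write_variant_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Greedy LD pruning to independent SNPs
#'
#' Scans the panel in genomic order and keeps a SNP iff its r2 with
#' every previously kept SNP does not exceed `r2_max` (pairs absent
#' from the table count as r2 = 0).  Removal is strict (`r2 > r2_max`):
#' a pair at exactly the threshold is retained, matching the usual
#' "remove r2 > 0.3" phrasing of GWAS pipelines.  The scan is
#' deterministic -- no randomness, no seed -- and idempotent.
#'
#' @param snps a [variant_panel()] (already sorted by chrom, pos; an
#'   unsorted data frame is rejected).
#' @param ld an [ld_table()].
#' @param r2_max pruning threshold (default 0.3).
#' @return The kept subset of `snps`, in original order.
#' @export
ld_prune <- function(snps, ld, r2_max = 0.3) {
  if (!inherits(snps, "variant_panel")) {
    stopifnot(is.data.frame(snps))
    ord <- order(snps$chrom, snps$pos, snps$snp_id)
    if (!identical(ord, seq_len(nrow(snps))))
      stop("'snps' must be sorted by (chrom, pos)")
    snps <- variant_panel(snps)
  }
  n <- nrow(snps)
  if (!n || !nrow(ld)) return(snps)
  idx <- .ld_index(ld)
  # per-SNP neighbour arrays resolved to row positions in `snps`
  row_of <- setNames(seq_len(n), snps$snp_id)
  kept <- logical(n)
  for (i in seq_len(n)) {
    rows <- idx[[snps$snp_id[i]]]
    if (is.null(rows)) { kept[i] <- TRUE; next }
    other <- ifelse(ld$snp_a[rows] == snps$snp_id[i],
                    ld$snp_b[rows], ld$snp_a[rows])
    oi <- row_of[other]
    high <- ld$r2[rows] > r2_max
    conflict <- any(high & !is.na(oi) & kept[ifelse(is.na(oi), 1L, oi)])
    kept[i] <- !conflict
  }
  out <- snps[kept, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_panel", "data.frame")
  out
}

#' Functional SNP map I/O
#'
#' A functional SNP map links SNPs to the genes they putatively
#' regulate (eQTL targets or regulatory-annotation assignments), with
#' an optional tissue or annotation-category label per record.
#'
#' @param df data frame with columns `snp_id`, `gene_id` and optional
#'   `category`.
#' @return Data frame of class `functional_snp_map`.
#' @export
functional_snp_map <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(c("snp_id", "gene_id"), names(df))
  if (length(missing_cols))
    stop("functional map columns missing: ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(snp_id = as.character(df$snp_id),
                    gene_id = as.character(df$gene_id),
                    category = if ("category" %in% names(df))
                      as.character(df$category) else NA_character_,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("functional_snp_map", "data.frame")
  out
}

#' @rdname functional_snp_map
#' @param path TSV with header `snp_id gene_id [category]`.
#' @export
read_functional_snp_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  functional_snp_map(read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
}

#' @rdname functional_snp_map
#' @param fmap map to write.
#' @export
write_functional_snp_map <- function(fmap, path) {
  write.table(as.data.frame(fmap), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Functional SNPs of a target gene set
#'
#' Selects all SNPs whose mapped gene set intersects the target genes.
#'
#' @param fmap a [functional_snp_map()].
#' @param targets character vector of target gene ids.
#' @return Character vector of SNP ids (unique, sorted).
#' @export
select_functional_snps_of_targets <- function(fmap, targets) {
  sort(unique(fmap$snp_id[fmap$gene_id %in% targets]))
}

#' GWAS summary I/O
#'
#' A GWAS summary maps SNP ids to association P-values in `(0, 1]`.
#'
#' @param df data frame with columns `snp_id`, `pvalue`.
#' @return Named numeric vector (names = snp ids).
#' @export
gwas_summary <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(c("snp_id", "pvalue"), names(df))
  if (length(missing_cols))
    stop("GWAS summary columns missing: ",
         paste(missing_cols, collapse = ", "))
  p <- as.numeric(df$pvalue)
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("GWAS P-values must lie in (0, 1]")
  ids <- as.character(df$snp_id)
  if (anyDuplicated(ids)) stop("duplicate snp_id in GWAS summary")
  setNames(p, ids)
}

#' @rdname gwas_summary
#' @param path TSV with header `snp_id pvalue`.
#' @export
read_gwas_summary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gwas_summary(read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))
}

#' @rdname gwas_summary
#' @param gwas named numeric vector as returned by [gwas_summary()].
#' @export
write_gwas_summary <- function(gwas, path) {
  write.table(data.frame(snp_id = names(gwas), pvalue = unname(gwas)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-sided Kolmogorov-Smirnov test for an excess of small values
#'
#' Tests whether the target sample is stochastically smaller than the
#' background using the one-sided statistic
#' `D+ = sup_x (F_target(x) - F_background(x))`, with the asymptotic
#' tail probability `exp(-2 D+^2 m n / (m + n))` clipped to `[0, 1]`.
#'
#' @param target_p,background_p non-empty numeric samples (here,
#'   association P-values).
#' @return List with elements `statistic` (D+) and `p`.
#' @export
ks_one_sided <- function(target_p, background_p) {
  if (!length(target_p) || !length(background_p))
    stop("both samples must be non-empty")
  m <- length(target_p)
  n <- length(background_p)
  xs <- sort(unique(c(target_p, background_p)))
  ft <- findInterval(xs, sort(target_p)) / m
  fb <- findInterval(xs, sort(background_p)) / n
  d <- max(0, ft - fb)
  p <- min(1, exp(-2 * d^2 * m * n / (m + n)))
  list(statistic = d, p = p)
}

#' Enrichment of low GWAS P-values in a target SNP set
#'
#' Builds the table `k` = target SNPs with `P < p_thresh`, `n` =
#' target SNPs, `K` = all tested SNPs with `P < p_thresh`, `N` = all
#' tested SNPs, and reports fold enrichment, a one-sided Fisher
#' P-value and a one-sided KS P-value comparing the target P-value
#' distribution against the full panel.  SNPs absent from the GWAS
#' summary are dropped (with a message reporting the count) before the
#' table is formed.
#'
#' @param all_snps character vector: the tested (typically LD-pruned)
#'   SNP panel.
#' @param target_snps character vector, a subset of `all_snps`.
#' @param gwas named numeric vector from [gwas_summary()].
#' @param p_thresh low-P threshold (default 0.01).
#' @param label result label.
#' @return An [enrichment_result()] with Fisher and KS P-values.
#' @export
low_p_enrichment <- function(all_snps, target_snps, gwas,
                             p_thresh = 0.01, label = "") {
  all_snps <- unique(as.character(all_snps))
  target_snps <- unique(as.character(target_snps))
  stray <- setdiff(target_snps, all_snps)
  if (length(stray))
    stop("target SNPs outside the tested panel: ",
         paste(head(stray, 5L), collapse = ", "))
  covered <- all_snps %in% names(gwas)
  n_dropped <- sum(!covered)
  if (n_dropped)
    message(sprintf("low_p_enrichment: dropping %d SNP(s) missing from the GWAS summary",
                    n_dropped))
  all_snps <- all_snps[covered]
  target_snps <- target_snps[target_snps %in% all_snps]
  p_all <- gwas[all_snps]
  p_tgt <- gwas[target_snps]
  tab <- contingency_table(sum(p_tgt < p_thresh), length(p_tgt),
                           sum(p_all < p_thresh), length(p_all))
  fold <- if (tab$n > 0 && tab$K > 0) fold_enrichment(tab) else NA_real_
  ks <- if (length(p_tgt) && length(p_all))
    ks_one_sided(p_tgt, p_all) else list(statistic = NA_real_, p = NA_real_)
  enrichment_result(table = tab, fold = fold,
                    fisher_p = fisher_one_sided(tab), ks_p = ks$p,
                    label = label,
                    extra = list(ks_statistic = ks$statistic,
                                 n_dropped = n_dropped,
                                 p_thresh = p_thresh))
}
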