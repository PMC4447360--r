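# Core 2x2 enrichment statistics shared by every analysis layer.

#' Construct a 2x2 enrichment contingency table
#'
#' The four counts describe a set-within-background design: `k` members
#' of the tested set that are "positive" (e.g. reach P < 0.01), `n` the
#' tested set size, `K` positives in the whole background and `N` the
#' background size.
#'
#' @param k,n,K,N non-negative integer counts with
#'   `k <= min(n, K)`, `n <= N`, `K <= N`.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(!is.finite(vals)) || any(vals < 0) ||
      any(vals != round(vals)))
    stop("contingency counts must be non-negative integers")
  if (k > n || k > K) stop("k must be <= min(n, K)")
  if (n > N || K > N) stop("n and K must be <= N")
  structure(list(k = as.numeric(k), n = as.numeric(n),
                 K = as.numeric(K), N = as.numeric(N)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: k=%g n=%g K=%g N=%g\n",
              x$k, x$n, x$K, x$N))
  invisible(x)
}

#' Fold enrichment of a contingency table
#'
#' The ratio of the in-set positive proportion to the background
#' positive proportion, `(k/n) / (K/N)`, identically equal to
#' `(k/K) / (n/N)`.
#'
#' @param t a [contingency_table()].
#' @return Non-negative numeric scalar.
#' @examples
#' fold_enrichment(contingency_table(548, 12362, 1488, 81223))  # 2.42
#' @export
fold_enrichment <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$n == 0 || t$K == 0)
    stop("fold enrichment undefined: n and K must be > 0")
  # single product form so (k/n)/(K/N) and (k/K)/(n/N) cannot drift
  (t$k * t$N) / (t$n * t$K)
}

#' One-sided (enrichment) Fisher exact test
#'
#' Returns `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the
#' probability of observing at least the attained overlap when `n`
#' items are drawn from a background of `N` containing `K` positives.
#' Computed through the exact hypergeometric tail, which stays accurate
#' for extreme enrichments (P-values far below 1e-100).
#'
#' @param t a [contingency_table()].
#' @return P-value in `[0, 1]`.
#' @export
fisher_one_sided <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  min(1, phyper(t$k - 1, t$K, t$N - t$K, t$n, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH q-values; a thin validated wrapper kept so every module
#' corrects multiplicity the same way.
#'
#' @param pvalues numeric vector of raw P-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) && (any(!is.finite(pvalues)) ||
                          any(pvalues < 0 | pvalues > 1)))
    stop("P-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Bundle the outputs of one enrichment test
#'
#' Container carrying the contingency table, fold enrichment and the
#' P-values produced by the applicable tests (Fisher always; KS and
#' permutation where computed).
#'
#' @param table a [contingency_table()] or `NULL` for tests without one
#'   (e.g. the LD permutation test).
#' @param fold fold enrichment (>= 0) or `NA`.
#' @param fisher_p,ks_p,perm_p probabilities in `[0, 1]` (`NA` when not
#'   applicable).
#' @param n_perms number of permutations behind `perm_p`; required
#'   whenever `perm_p` is given.
#' @param label result label.
#' @param extra named list of additional metadata.
#' @return Object of class `enrichment_result`.
#' @export
enrichment_result <- function(table = NULL, fold = NA_real_,
                              fisher_p = NA_real_, ks_p = NA_real_,
                              perm_p = NA_real_, n_perms = NA_integer_,
                              label = "", extra = list()) {
  probs <- c(fisher_p, ks_p, perm_p)
  if (any(!is.na(probs) & (probs < 0 | probs > 1)))
    stop("P-values must lie in [0, 1]")
  if (!is.na(fold) && fold < 0) stop("fold must be >= 0")
  if (!is.na(perm_p) && is.na(n_perms))
    stop("perm_p requires n_perms")
  structure(list(table = table, fold = fold, fisher_p = fisher_p,
                 ks_p = ks_p, perm_p = perm_p, n_perms = n_perms,
                 label = label, extra = extra),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result '%s'\n", x$label))
  if (!is.null(x$table))
    cat(sprintf("  k/n = %g/%g, K/N = %g/%g\n",
                x$table$k, x$table$n, x$table$K, x$table$N))
  cat(sprintf("  fold = %s, fisher_p = %s",
              format(x$fold, digits = 3), format(x$fisher_p, digits = 3)))
  if (!is.na(x$ks_p)) cat(sprintf(", ks_p = %s", format(x$ks_p, digits = 3)))
  if (!is.na(x$perm_p))
    cat(sprintf(", perm_p = %s (%d perms)", format(x$perm_p, digits = 3),
                as.integer(x$n_perms)))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(label = x$label,
             k = if (is.null(x$table)) NA_real_ else x$table$k,
             n = if (is.null(x$table)) NA_real_ else x$table$n,
             K = if (is.null(x$table)) NA_real_ else x$table$K,
             N = if (is.null(x$table)) NA_real_ else x$table$N,
             fold = x$fold, fisher_p = x$fisher_p, ks_p = x$ks_p,
             perm_p = x$perm_p, n_perms = x$n_perms,
             stringsAsFactors = FALSE)
}

#' Enrichment of a target gene set across a collection of gene sets
#'
#' For each named set, builds the table `k = |set & target|`,
#' `n = |set|`, `K = |target|`, `N = |background|` and reports fold
#' enrichment with a one-sided Fisher P-value.  Covers co-expression
#' module enrichment and confounding checks against pooled GWAS genes.
#'
#' @param target character vector of target genes (subset of
#'   `background`).
#' @param sets named list of character vectors, each a subset of
#'   `background`.
#' @param background character vector: the gene universe.
#' @param fdr if `TRUE`, append BH q-values across the sets.
#' @return Data frame with one row per set: `label`, `k`, `n`, `K`,
#'   `N`, `fold`, `fisher_p` (and `q_value` with `fdr = TRUE`).
#' @export
gene_set_enrichment <- function(target, sets, background, fdr = FALSE) {
  background <- unique(background)
  target <- unique(target)
  stray <- setdiff(target, background)
  if (length(stray))
    stop("target genes outside background: ",
         paste(head(stray, 5L), collapse = ", "))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list")
  for (nm in names(sets)) {
    stray <- setdiff(sets[[nm]], background)
    if (length(stray))
      stop(sprintf("set '%s' has genes outside background: %s", nm,
                   paste(head(stray, 5L), collapse = ", ")))
  }
  N <- length(background)
  K <- length(target)
  rows <- lapply(names(sets), function(nm) {
    s <- unique(sets[[nm]])
    tab <- contingency_table(length(intersect(s, target)), length(s), K, N)
    data.frame(label = nm, k = tab$k, n = tab$n, K = tab$K, N = tab$N,
               fold = if (tab$n > 0 && tab$K > 0)
                 fold_enrichment(tab) else NA_real_,
               fisher_p = fisher_one_sided(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (fdr) out$q_value <- bh_fdr(out$fisher_p)
  out
}

#' Peak co-occurrence enrichment against an open-chromatin background
#'
#' Each open-chromatin region (ATAC-seq or DNase-hypersensitivity peak)
#' is classified by whether it overlaps (>= 1 bp) a peak of set `a` and
#' of set `b`.  The resulting 2x2 table (`k` = both, `n` = overlaps
#' `b`, `K` = overlaps `a`, `N` = all regions) is scored with fold
#' enrichment and a one-sided Fisher test, asking whether `a` and `b`
#' co-occur in open chromatin more than expected.
#'
#' @param oc open-chromatin background [peak_set()]; must be non-empty.
#'   Any confidence filter (e.g. a fold-enrichment floor on ATAC peaks)
#'   is applied by the caller before this test.
#' @param a,b [peak_set()] objects on the same build as `oc`.
#' @return An [enrichment_result()].
#' @export
open_chromatin_overlap_enrichment <- function(oc, a, b) {
  .check_same_build(oc, a)
  .check_same_build(oc, b)
  if (!nrow(oc)) stop("open-chromatin background is empty")
  gr_oc <- .as_granges(oc)
  in_a <- suppressWarnings(
    GenomicRanges::countOverlaps(gr_oc, .as_granges(a))) > 0
  in_b <- suppressWarnings(
    GenomicRanges::countOverlaps(gr_oc, .as_granges(b))) > 0
  tab <- contingency_table(sum(in_a & in_b), sum(in_b), sum(in_a),
                           nrow(oc))
  fold <- if (tab$n > 0 && tab$K > 0) fold_enrichment(tab)
          else if (tab$k == 0) 0 else NA_real_
  enrichment_result(table = tab, fold = fold,
                    fisher_p = fisher_one_sided(tab),
                    label = sprintf("%s~%s|%s", set_label(a),
                                    set_label(b), set_label(oc)))
}
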