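# Trait catalogs and the matched-size gene-set permutation test.

#' Construct a trait catalog
#'
#' A trait catalog maps each trait to its set of candidate genes; the
#' pooled union of all trait genes serves as the enrichment background
#' ("all GWAS genes").
#'
#' @param traits named list of character vectors (trait -> gene set).
#'   Genes appearing under several traits are counted once per trait
#'   set (sets, not multisets).
#' @param extra_genes optional named list merged into the matching
#'   trait sets and the pool (e.g. consortium genes absent from the
#'   catalog snapshot).
#' @return Object of class `trait_catalog`: list with elements
#'   `traits` (named list) and `pool` (character).
#' @export
trait_catalog <- function(traits, extra_genes = NULL) {
  if (!is.list(traits) || is.null(names(traits)) ||
      any(!nzchar(names(traits))))
    stop("'traits' must be a named list of gene sets")
  if (anyDuplicated(names(traits))) stop("trait labels must be unique")
  traits <- lapply(traits, function(g) sort(unique(as.character(g))))
  if (!is.null(extra_genes)) {
    if (!is.list(extra_genes) || is.null(names(extra_genes)))
      stop("'extra_genes' must be a named list")
    for (nm in names(extra_genes)) {
      add <- as.character(extra_genes[[nm]])
      traits[[nm]] <- sort(unique(c(traits[[nm]], add)))
    }
  }
  structure(list(traits = traits,
                 pool = sort(unique(unlist(traits, use.names = FALSE)))),
            class = "trait_catalog")
}

#' @export
print.trait_catalog <- function(x, ...) {
  cat(sprintf("trait_catalog: %d traits, %d pooled genes\n",
              length(x$traits), length(x$pool)))
  invisible(x)
}

#' Trait labels of a catalog
#' @param cat a [trait_catalog()].
#' @export
catalog_traits <- function(cat) names(cat$traits)

#' Parse a GWAS-catalog-style table into a trait catalog
#'
#' Reads a TSV with columns `trait`, `gene` (possibly multi-valued,
#' separated by `,` or `;`) and `ancestry`, dedupes each trait's gene
#' set and pools the union as background.  With `require_european`
#' records whose ancestry field does not mention a European cohort are
#' excluded, mirroring the usual restriction of LD-based analyses to
#' European-ancestry studies.
#'
#' @param path TSV file path.
#' @param require_european drop non-European records (default `TRUE`).
#' @param extra_genes optional named list of supplementary genes per
#'   trait (added to the trait and the pool).
#' @return A [trait_catalog()].
#' @export
parse_gwas_catalog <- function(path, require_european = TRUE,
                               extra_genes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "")
  missing_cols <- setdiff(c("trait", "gene", "ancestry"), names(df))
  if (length(missing_cols))
    stop("catalog columns missing: ",
         paste(missing_cols, collapse = ", "))
  if (require_european) {
    keep <- grepl("european", df$ancestry, ignore.case = TRUE) &
      !grepl("non[- ]?european", df$ancestry, ignore.case = TRUE)
    df <- df[keep, , drop = FALSE]
  }
  genes <- strsplit(df$gene, "[,;][[:space:]]*")
  reps <- lengths(genes)
  long <- data.frame(trait = rep(df$trait, reps),
                     gene = trimws(unlist(genes)),
                     stringsAsFactors = FALSE)
  long <- long[nzchar(long$gene), , drop = FALSE]
  trait_catalog(split(long$gene, long$trait), extra_genes = extra_genes)
}

#' Enrichment of a target gene set in one trait's genes
#'
#' Tests whether a trait's candidate genes are enriched for target
#' genes, against the pooled all-GWAS-gene background: `k` = trait
#' genes that are targets, `n` = trait genes, `K` = targets present in
#' the pool, `N` = pool size.
#'
#' @param targets character vector of target genes (intersected with
#'   the pool before testing).
#' @param cat a [trait_catalog()].
#' @param trait trait label present in `cat`.
#' @return An [enrichment_result()].
#' @export
trait_enrichment <- function(targets, cat, trait) {
  stopifnot(inherits(cat, "trait_catalog"))
  if (!trait %in% names(cat$traits)) stop("unknown trait: ", trait)
  targets <- intersect(unique(targets), cat$pool)
  genes <- cat$traits[[trait]]
  tab <- contingency_table(length(intersect(genes, targets)),
                           length(genes), length(targets),
                           length(cat$pool))
  fold <- if (tab$n > 0 && tab$K > 0) fold_enrichment(tab) else NA_real_
  enrichment_result(table = tab, fold = fold,
                    fisher_p = fisher_one_sided(tab), label = trait)
}

#' Permutation specification
#'
#' @param n_perms number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @param comparison how a null P-value beats the observed one:
#'   `"strict_less"` (gene-level convention: count null P strictly
#'   smaller) or `"greater_equal"` (statistic-level convention: count
#'   null statistic at or above the observed).
#' @return Object of class `permutation_spec`.
#' @export
permutation_spec <- function(n_perms = 1000L, seed = 1L,
                             comparison = c("strict_less",
                                            "greater_equal")) {
  comparison <- match.arg(comparison)
  if (!is.numeric(n_perms) || n_perms < 1)
    stop("n_perms must be >= 1")
  structure(list(n_perms = as.integer(n_perms),
                 seed = as.integer(seed), comparison = comparison),
            class = "permutation_spec")
}

#' Matched-size permutation enrichment of a trait gene set
#'
#' Corrects the Fisher enrichment P-value of [trait_enrichment()] for
#' trait-set size: `n_perms` random gene sets of the same size as the
#' trait are drawn uniformly without replacement from the pooled
#' background, each is scored with the same one-sided Fisher test, and
#' the permutation P-value is the proportion of random sets whose
#' Fisher P-value is strictly smaller than the trait's.  A zero count
#' is displayed as a floor (e.g. `<1.0e-03` at 1000 permutations).
#'
#' @inheritParams trait_enrichment
#' @param spec a [permutation_spec()]; draws are reproducible
#'   bit-exactly given (seed, pool order).
#' @return An [enrichment_result()] whose `extra` carries
#'   `avg_perm_fold` (mean fold across permuted sets, close to 1 for
#'   matched sizes), `perm_p_display` and the permutation counts.
#' @export
permutation_enrichment <- function(targets, cat, trait,
                                   spec = permutation_spec()) {
  stopifnot(inherits(cat, "trait_catalog"),
            inherits(spec, "permutation_spec"))
  obs <- trait_enrichment(targets, cat, trait)
  pool <- cat$pool
  N <- length(pool)
  n <- obs$table$n
  if (n > N) stop("trait set larger than the pool")
  K <- obs$table$K
  is_target <- pool %in% targets
  set.seed(spec$seed)
  ks <- vapply(seq_len(spec$n_perms),
               function(i) sum(is_target[sample.int(N, n)]),
               numeric(1))
  p_rand <- phyper(ks - 1, K, N - K, n, lower.tail = FALSE)
  hits <- switch(spec$comparison,
                 strict_less = sum(p_rand < obs$fisher_p),
                 greater_equal = sum(p_rand >= obs$fisher_p))
  perm_p <- hits / spec$n_perms
  folds <- (ks / n) / (K / N)
  enrichment_result(
    table = obs$table, fold = obs$fold, fisher_p = obs$fisher_p,
    perm_p = perm_p, n_perms = spec$n_perms, label = trait,
    extra = list(avg_perm_fold = mean(folds),
                 n_hits = hits,
                 comparison = spec$comparison,
                 perm_p_display = format_perm_p(perm_p, spec$n_perms)))
}

#' Display form of a permutation P-value
#'
#' Zero exceedance counts are reported as a resolution floor
#' (`"<1.0e-03"` at 1000 permutations) since the test cannot resolve
#' below `1/n_perms`.
#'
#' @param perm_p permutation P-value.
#' @param n_perms number of permutations.
#' @return Character scalar.
#' @export
format_perm_p <- function(perm_p, n_perms) {
  if (is.na(perm_p)) return(NA_character_)
  if (perm_p == 0) sprintf("<%.1e", 1 / n_perms)
  else format(perm_p, digits = 3)
}

#' Combined two-test significance call
#'
#' A trait is deemed significant when it passes `alpha` in both the
#' gene-level matched-size permutation test and the SNP-level LD
#' permutation test (strict `<` in each), giving a combined cutoff of
#' `alpha^2`.  A missing P-value on either side yields `NA`
#' (indeterminate), not `FALSE`.
#'
#' @param gene_perm_p,snp_perm_p numeric vectors of permutation
#'   P-values (recycled to common length).
#' @param alpha per-test threshold (default 0.05).
#' @return Logical vector (with `NA` for indeterminate traits).
#' @export
combined_significance <- function(gene_perm_p, snp_perm_p,
                                  alpha = 0.05) {
  ifelse(is.na(gene_perm_p) | is.na(snp_perm_p), NA,
         gene_perm_p < alpha & snp_perm_p < alpha)
}
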