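# Gene annotation and peak-to-gene assignment.

#' Construct or read a gene annotation table
#'
#' A gene annotation is a data frame with one row per gene: `gene_id`
#' (unique), `chrom`, `tss` (transcription start site, base position)
#' and `strand` (`+`/`-`).  Strand is carried for bookkeeping but plays
#' no role in distance computation.
#'
#' @param df data frame with the four columns above.
#' @return Validated annotation data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("gene_id", "chrom", "tss", "strand")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("annotation columns missing: ", paste(missing_cols, collapse = ", "))
  out <- data.frame(gene_id = as.character(df$gene_id),
                    chrom = as.character(df$chrom),
                    tss = as.numeric(df$tss),
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in annotation")
  if (nrow(out) && any(out$tss < 0)) stop("tss must be >= 0")
  if (nrow(out) && !all(out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' @rdname gene_annotation
#' @param path TSV file with header `gene_id chrom tss strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  gene_annotation(df)
}

#' @rdname gene_annotation
#' @param genes annotation to write.
#' @export
write_gene_annotation <- function(genes, path) {
  write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Assign target genes to peaks by TSS distance
#'
#' Distance is measured from the peak midpoint to the gene TSS,
#' ignoring strand.  Under `"single_nearest"` each peak maps to the one
#' gene with minimal distance, provided that distance does not exceed
#' `max_dist`; ties break to the gene with the smaller TSS coordinate,
#' then the lexicographically smaller `gene_id`.  Under `"all_within"`
#' each peak maps to every gene within `max_dist`.  Peaks with no gene
#' in range are simply absent from the map.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_annotation()].
#' @param rule `"single_nearest"` (default) or `"all_within"`.
#' @param max_dist distance bound in bp (default 50 kb).
#' @return A `peak_gene_map`: data frame with columns `peak_id`,
#'   `gene_id`, `distance`, carrying the rule and bound as attributes.
#' @export
assign_genes <- function(peaks, genes,
                         rule = c("single_nearest", "all_within"),
                         max_dist = 50000) {
  rule <- match.arg(rule)
  stopifnot(inherits(peaks, "peak_set"))
  if (!nrow(genes)) stop("gene annotation is empty")
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(peaks))
    return(structure(empty, rule = rule, max_dist = max_dist,
                     class = c("peak_gene_map", "data.frame")))
  mid <- (peaks$start + peaks$end) / 2
  win <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = pmax(0, ceiling(mid - max_dist)) + 1,
                              end = floor(mid + max_dist) + 1))
  tss_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$tss + 1, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(win, tss_gr))
  if (!length(hits))
    return(structure(empty, rule = rule, max_dist = max_dist,
                     class = c("peak_gene_map", "data.frame")))
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  dist <- abs(genes$tss[gi] - mid[pi])
  keep <- dist <= max_dist
  pi <- pi[keep]; gi <- gi[keep]; dist <- dist[keep]
  df <- data.frame(peak_id = peaks$name[pi],
                   gene_id = genes$gene_id[gi],
                   distance = dist,
                   tss = genes$tss[gi],
                   stringsAsFactors = FALSE)
  if (rule == "single_nearest" && nrow(df)) {
    ord <- order(df$peak_id, df$distance, df$tss, df$gene_id)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$peak_id), , drop = FALSE]
  }
  df$tss <- NULL
  df <- df[order(df$peak_id, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, rule = rule, max_dist = max_dist,
            class = c("peak_gene_map", "data.frame"))
}

#' Forward and inverse views of a peak-gene map
#'
#' `peak_genes()` lists gene sets per peak; `gene_peaks()` is the exact
#' transpose, listing peak sets per gene.
#'
#' @param map a `peak_gene_map` from [assign_genes()].
#' @return Named list of character vectors.
#' @export
peak_genes <- function(map) {
  lapply(split(map$gene_id, map$peak_id), unique)
}

#' @rdname peak_genes
#' @export
gene_peaks <- function(map) {
  lapply(split(map$peak_id, map$gene_id), unique)
}

#' Target genes of a peak-gene map
#' @param map a `peak_gene_map`.
#' @return Sorted character vector of distinct assigned genes.
#' @export
target_genes <- function(map) sort(unique(map$gene_id))

#' Write / read a peak-gene map as two-column TSV
#' @param map a `peak_gene_map`.
#' @param path file path.
#' @export
write_peak_gene_map <- function(map, path) {
  write.table(as.data.frame(map)[, c("peak_id", "gene_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise a peak set and its gene assignments
#'
#' Mirrors the usual per-antibody summary of a ChIP-seq experiment:
#' peak count, mean peak length, number of distinct target genes,
#' number of genes mapped by more than one peak, and number of peaks
#' mapped to more than one gene.
#'
#' @param peaks a [peak_set()].
#' @param map a `peak_gene_map` for those peaks.
#' @return One-row data frame with columns `label`, `n_peaks`,
#'   `mean_length`, `n_target_genes`, `n_genes_multi_peak`,
#'   `n_peaks_multi_gene`.
#' @export
peak_summary <- function(peaks, map) {
  n <- nrow(peaks)
  mean_len <- if (n) mean(peaks$end - peaks$start) else 0
  by_gene <- gene_peaks(map)
  by_peak <- peak_genes(map)
  data.frame(
    label = set_label(peaks),
    n_peaks = n,
    mean_length = mean_len,
    n_target_genes = length(by_gene),
    n_genes_multi_peak = sum(lengths(by_gene) > 1L),
    n_peaks_multi_gene = sum(lengths(by_peak) > 1L),
    stringsAsFactors = FALSE)
}
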