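# Genomic interval data model and BED I/O.
#
# All coordinates are BED-style: 0-based, half-open [start, end).  A
# peak_set is a plain data frame of intervals plus a label and a genome
# build tag; interval operations are delegated to GenomicRanges, with a
# +1 shift on conversion because GRanges is 1-based closed.

#' Construct a peak set
#'
#' A `peak_set` is a named, sorted collection of genomic intervals on a
#' shared genome build, typically the peaks of one ChIP-seq experiment.
#' Intervals use BED conventions: 0-based, half-open `[start, end)`.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end` and
#'   optionally `name` (identifier) and `score` (ranking value, e.g. a
#'   peak Q-value where smaller is better).
#' @param label non-empty character scalar naming the set.
#' @param genome_build character tag; sets can only be combined when
#'   their builds agree.
#' @return An object of class `peak_set`: the interval data frame
#'   (sorted by chromosome then start, zero-length intervals rejected)
#'   with attributes `label` and `genome_build`.
#' @examples
#' ps <- peak_set(data.frame(chrom = "chr1", start = 100, end = 200),
#'                label = "Ab1")
#' @export
peak_set <- function(intervals, label, genome_build = "unspecified") {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a non-empty character scalar")
  stopifnot(is.data.frame(intervals))
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(intervals))
  if (length(missing_cols))
    stop("interval columns missing: ", paste(missing_cols, collapse = ", "))
  nr <- nrow(intervals)
  df <- data.frame(
    chrom = as.character(intervals$chrom),
    start = as.numeric(intervals$start),
    end   = as.numeric(intervals$end),
    name  = if ("name" %in% names(intervals))
      as.character(intervals$name) else rep(NA_character_, nr),
    score = if ("score" %in% names(intervals))
      as.numeric(intervals$score) else rep(NA_real_, nr),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$start < 0)) stop("interval start must be >= 0")
    if (any(df$start >= df$end))
      stop("zero- or negative-length interval: start must be < end")
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    auto <- is.na(df$name) | !nzchar(df$name)
    df$name[auto] <- sprintf("%s:%d-%d", df$chrom[auto],
                             as.integer(df$start[auto]),
                             as.integer(df$end[auto]))
  }
  structure(df, label = label, genome_build = genome_build,
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s' (%s): %d intervals\n",
              attr(x, "label"), attr(x, "genome_build"), nrow(x)))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Label and genome build of a peak set
#' @param x a [peak_set()].
#' @return Character scalar.
#' @export
set_label <- function(x) attr(x, "label")

#' @rdname set_label
#' @export
genome_build <- function(x) attr(x, "genome_build")

# BED half-open -> GRanges (1-based closed)
.as_granges <- function(ps) {
  GenomicRanges::GRanges(
    seqnames = ps$chrom,
    ranges = IRanges::IRanges(start = ps$start + 1L, end = ps$end)
  )
}

.check_same_build <- function(a, b) {
  if (!identical(genome_build(a), genome_build(b)))
    stop(sprintf("genome build mismatch: '%s' vs '%s'",
                 genome_build(a), genome_build(b)))
}

#' Read a BED file into a peak set
#'
#' Accepts BED3 (chrom, start, end) and wider forms; column 4 is taken
#' as the interval name and column 5 as the score.  Coordinates are
#' interpreted as BED 0-based half-open.
#'
#' @param path path to a tab-separated BED file without header.
#' @param label set label; defaults to the file name without extension.
#' @param genome_build genome build tag.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, label = NULL,
                     genome_build = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(peak_set(
    data.frame(chrom = character(), start = numeric(), end = numeric()),
    label = label, genome_build = genome_build))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(sprintf("malformed BED line %d: fewer than 3 fields", bad[1L]))
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  ends   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad))
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad[1L]))
  bad <- which(starts >= ends)
  if (length(bad))
    stop(sprintf("invalid interval at line %d: start >= end", bad[1L]))
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = starts, end = ends, stringsAsFactors = FALSE)
  if (all(nf >= 4L))
    df$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L))
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  peak_set(df, label = label, genome_build = genome_build)
}

#' Write a peak set to BED
#'
#' Emits BED3 when neither names nor scores are present, BED4/BED5
#' otherwise.  Round-trips coordinates bit-exactly with [read_bed()].
#'
#' @param ps a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ps, path) {
  df <- as.data.frame(ps)
  out <- data.frame(chrom = df$chrom,
                    start = format(df$start, scientific = FALSE, trim = TRUE),
                    end = format(df$end, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE)
  has_score <- nrow(df) > 0 && !all(is.na(df$score))
  has_name <- nrow(df) > 0 && (!all(is.na(df$name)) || has_score)
  if (has_name) out$name <- ifelse(is.na(df$name), ".", df$name)
  if (has_score) out$score <- ifelse(is.na(df$score), ".",
                                     format(df$score, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Intersect two peak sets under the containment/overlap rule
#'
#' Consolidates two antibody peak sets into a shared set: for every
#' overlapping pair of peaks the output contains the smaller peak when
#' one fully contains the other (which equals their intersection), and
#' the region of overlap when the overlap is partial.  Non-overlapping
#' peaks are dropped; exact duplicate output intervals are collapsed.
#'
#' @param a,b [peak_set()] objects on the same genome build.
#' @param label label for the result; default concatenates the inputs.
#' @return A sorted, deduplicated [peak_set()].
#' @examples
#' a <- peak_set(data.frame(chrom = "chr1", start = 100, end = 300), "a")
#' b <- peak_set(data.frame(chrom = "chr1", start = 150, end = 250), "b")
#' intersect_peak_sets(a, b)  # the contained peak [150, 250)
#' @export
intersect_peak_sets <- function(a, b, label = NULL) {
  .check_same_build(a, b)
  if (is.null(label))
    label <- paste0(set_label(a), ".", set_label(b), ".shared")
  if (!nrow(a) || !nrow(b))
    return(peak_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()),
                    label = label, genome_build = genome_build(a)))
  gra <- .as_granges(a)
  grb <- .as_granges(b)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gra, grb))
  if (!length(hits))
    return(peak_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()),
                    label = label, genome_build = genome_build(a)))
  ov <- GenomicRanges::pintersect(gra[S4Vectors::queryHits(hits)],
                                  grb[S4Vectors::subjectHits(hits)])
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ov)),
    start = GenomicRanges::start(ov) - 1,
    end   = GenomicRanges::end(ov),
    stringsAsFactors = FALSE)
  df <- unique(df)
  peak_set(df, label = label, genome_build = genome_build(a))
}

#' Enumerate overlapping peak pairs between two sets
#'
#' Reports every (a-interval, b-interval) pair sharing at least
#' `min_bp` bases under half-open coordinates.  Symmetric under
#' argument swap (with columns exchanged).
#'
#' @param a,b [peak_set()] objects on the same genome build.
#' @param min_bp minimum shared bases (>= 1).
#' @return Data frame with columns `a_name`, `b_name`, `overlap_bp`.
#' @export
overlap_pairs <- function(a, b, min_bp = 1L) {
  .check_same_build(a, b)
  if (!is.numeric(min_bp) || length(min_bp) != 1L || min_bp < 1)
    stop("'min_bp' must be a single integer >= 1")
  empty <- data.frame(a_name = character(), b_name = character(),
                      overlap_bp = numeric(), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  gra <- .as_granges(a)
  grb <- .as_granges(b)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gra, grb,
                                minoverlap = as.integer(min_bp)))
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ovbp <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  data.frame(a_name = a$name[qi], b_name = b$name[si],
             overlap_bp = ovbp, stringsAsFactors = FALSE)
}

#' Select the top-ranked peaks of a set
#'
#' Keeps the `n` best-ranked intervals, where a smaller score (e.g. a
#' peak-calling Q-value) is better.  Ties at the cutoff break
#' deterministically by (chrom, start).  If the set has at most `n`
#' peaks it is returned unchanged.
#'
#' @param ps a [peak_set()] whose intervals all carry a score.
#' @param n number of peaks to keep.
#' @return A [peak_set()].
#' @export
select_top_peaks <- function(ps, n) {
  stopifnot(inherits(ps, "peak_set"), is.numeric(n), n >= 0)
  if (nrow(ps) && any(is.na(ps$score)))
    stop("select_top_peaks requires a score on every interval")
  if (nrow(ps) <= n) return(ps)
  ord <- order(ps$score, ps$chrom, ps$start)
  keep <- sort(ord[seq_len(n)])
  peak_set(as.data.frame(ps)[keep, , drop = FALSE],
           label = set_label(ps), genome_build = genome_build(ps))
}
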