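# Sparse pairwise-r2 tables.
#
# An ld_table stores unordered SNP pairs with their squared allelic
# correlation.  Pairs are canonicalised (snp_a < snp_b) so the table is
# symmetric by construction; absent pairs are read as r2 = 0.

#' Construct a sparse LD table
#'
#' @param snp_a,snp_b character vectors of SNP identifiers (pairwise).
#' @param r2 squared correlations in `[0, 1]`.
#' @param source label for the r2 source (e.g. `"hapmap_ceu"`,
#'   `"kg_eur"`, `"merged"`).
#' @return Object of class `ld_table`: data frame `snp_a`, `snp_b`,
#'   `r2` with canonical pair order and a `source` attribute.
#' @export
ld_table <- function(snp_a = character(), snp_b = character(),
                     r2 = numeric(), source = "unspecified") {
  stopifnot(length(snp_a) == length(snp_b),
            length(snp_a) == length(r2))
  snp_a <- as.character(snp_a)
  snp_b <- as.character(snp_b)
  r2 <- as.numeric(r2)
  if (length(r2) && (any(!is.finite(r2)) || any(r2 < 0 | r2 > 1)))
    stop("r2 values must lie in [0, 1]")
  if (any(snp_a == snp_b)) stop("self pairs are not allowed")
  swap <- snp_a > snp_b
  tmp <- snp_a[swap]; snp_a[swap] <- snp_b[swap]; snp_b[swap] <- tmp
  df <- data.frame(snp_a = snp_a, snp_b = snp_b, r2 = r2,
                   stringsAsFactors = FALSE)
  key <- paste(df$snp_a, df$snp_b, sep = "\r")
  if (anyDuplicated(key)) {
    if (max(tapply(df$r2, key, function(v) diff(range(v)))) > 0)
      stop("conflicting r2 values for a duplicated pair")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df <- df[order(df$snp_a, df$snp_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, source = source, class = c("ld_table", "data.frame"))
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("ld_table (%s): %d pairs\n", attr(x, "source"), nrow(x)))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Source label of an LD table
#' @param ld an [ld_table()].
#' @export
ld_source <- function(ld) attr(ld, "source")

#' Read / write an LD table as TSV `snp_a snp_b r2`
#' @param path file path.
#' @param source source label for the table read.
#' @export
read_ld_table <- function(path, source = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  ld_table(df$snp_a, df$snp_b, df$r2, source = source)
}

#' @rdname read_ld_table
#' @param ld an [ld_table()].
#' @export
write_ld_table <- function(ld, path) {
  write.table(as.data.frame(ld), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Look up pairwise r2 values
#'
#' @param ld an [ld_table()].
#' @param a,b SNP identifier vectors (recycled pairwise).
#' @return Numeric vector; absent pairs give 0.
#' @export
ld_lookup <- function(ld, a, b) {
  a <- as.character(a); b <- as.character(b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  tab_key <- paste(ld$snp_a, ld$snp_b, sep = "\r")
  val <- ld$r2[match(key, tab_key)]
  val[is.na(val)] <- 0
  val
}

# Adjacency index: for each SNP, integer row indices of its pairs.
.ld_index <- function(ld) {
  n <- nrow(ld)
  if (!n) return(list())
  rows <- c(seq_len(n), seq_len(n))
  snps <- c(ld$snp_a, ld$snp_b)
  split(rows, snps)
}

#' Merge two r2 sources
#'
#' Combines two LD tables into one: a pair present in both takes the
#' arithmetic mean of its two r2 values, a pair present in only one
#' keeps that value, and pairs absent from both stay absent.  The merge
#' is commutative.
#'
#' @param a,b [ld_table()] objects.
#' @param source label for the merged table (default `"merged"`).
#' @return An [ld_table()].
#' @export
merge_r2_sources <- function(a, b, source = "merged") {
  stopifnot(inherits(a, "ld_table"), inherits(b, "ld_table"))
  ka <- paste(a$snp_a, a$snp_b, sep = "\r")
  kb <- paste(b$snp_a, b$snp_b, sep = "\r")
  keys <- union(ka, kb)
  va <- a$r2[match(keys, ka)]
  vb <- b$r2[match(keys, kb)]
  merged <- ifelse(is.na(va), vb, ifelse(is.na(vb), va, (va + vb) / 2))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  ld_table(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L),
           merged, source = source)
}
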