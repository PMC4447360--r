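# Shared builders and independent oracles.

ps <- function(chrom, start, end, ..., label = "test",
               build = "sim1") {
  peak_set(data.frame(chrom = chrom, start = start, end = end, ...),
           label = label, genome_build = build)
}

tiny_genes <- function(tss, chrom = "chr1",
                       ids = sprintf("g%02d", seq_along(tss))) {
  gene_annotation(data.frame(gene_id = ids, chrom = chrom, tss = tss,
                             strand = "+"))
}

# independent hypergeometric tail oracle: explicit binomial-coefficient
# enumeration of P(X >= k), never via phyper
enum_upper_tail <- function(k, n, K, N) {
  ks <- seq(max(k, 0, n + K - N), min(n, K))
  if (k > min(n, K)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# uniform random peak data frame (possibly overlapping intervals)
random_intervals <- function(n, chrom_n = 2, len_max = 50,
                             span = 1000) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = sample(sprintf("chr%d", seq_len(chrom_n)), n,
                            replace = TRUE),
             start = start,
             end = start + sample.int(len_max, n, replace = TRUE))
}
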