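test_that("read_bed parses BED3/BED6 with 0-based half-open coordinates", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t50\t80", "chr2\t0\t10"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 3L)
  expect_equal(x$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(x$start, c(50, 100, 0))  # sorted
  expect_equal(x$end, c(80, 200, 10))

  f6 <- withr::local_tempfile()
  writeLines("chr1\t100\t200\tpk1\t7.5\t+", f6)
  y <- read_bed(f6)
  expect_equal(y$name, "pk1")
  expect_equal(y$score, 7.5)

  fe <- withr::local_tempfile()
  writeLines(character(), fe)
  expect_equal(nrow(read_bed(fe)), 0L)
})

test_that("read_bed rejects malformed lines with a line number", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t300"), f)
  expect_error(read_bed(f), "line 2")
  f2 <- withr::local_tempfile()
  writeLines("chr1\t200\t100", f2)
  expect_error(read_bed(f2), "start >= end")
})

test_that("BED round-trip reproduces coordinates bit-exactly", {
  set.seed(41)
  x <- peak_set(random_intervals(60), label = "rt")
  f <- withr::local_tempfile()
  write_bed(x, f)
  y <- read_bed(f, label = "rt")
  expect_identical(as.data.frame(y)[c("chrom", "start", "end")],
                   as.data.frame(x)[c("chrom", "start", "end")])
})

test_that("intersection keeps the contained peak or the overlap region", {
  a <- ps("chr1", 100, 300)
  b <- ps("chr1", 150, 250)
  sh <- intersect_peak_sets(a, b)
  expect_equal(as.data.frame(sh)[c("start", "end")],
               data.frame(start = 150, end = 250))
  # equal intervals -> that interval once
  expect_equal(nrow(intersect_peak_sets(a, a)), 1L)

  sh2 <- intersect_peak_sets(ps("chr1", 100, 250), ps("chr1", 200, 350))
  expect_equal(c(sh2$start, sh2$end), c(200, 250))

  expect_equal(nrow(intersect_peak_sets(ps("chr1", 100, 200),
                                        ps("chr1", 300, 400))), 0L)
  expect_error(intersect_peak_sets(ps("chr1", 1, 2, build = "hg19"),
                                   ps("chr1", 1, 2, build = "hg38")),
               "build mismatch")
})

test_that("every intersection interval is contained in a peak of each input", {
  set.seed(7)
  for (rep in 1:10) {
    a <- peak_set(random_intervals(30), label = "a")
    b <- peak_set(random_intervals(30), label = "b")
    sh <- intersect_peak_sets(a, b)
    if (!nrow(sh)) next
    for (i in seq_len(nrow(sh))) {
      in_a <- any(a$chrom == sh$chrom[i] & a$start <= sh$start[i] &
                    a$end >= sh$end[i])
      in_b <- any(b$chrom == sh$chrom[i] & b$start <= sh$start[i] &
                    b$end >= sh$end[i])
      expect_true(in_a && in_b)
    }
  }
  # when each b peak lies inside a single a peak the output cannot
  # outnumber the smaller set
  a <- ps("chr1", c(0, 100, 200), c(50, 150, 250))
  b <- ps("chr1", c(10, 210), c(40, 230))
  expect_lte(nrow(intersect_peak_sets(a, b)), min(nrow(a), nrow(b)))
})

test_that("overlap_pairs honours the half-open convention and min_bp", {
  a <- ps("chr1", 100, 200)
  expect_equal(nrow(overlap_pairs(a, ps("chr1", 199, 300))), 1L)
  expect_equal(overlap_pairs(a, ps("chr1", 199, 300))$overlap_bp, 1)
  expect_equal(nrow(overlap_pairs(a, ps("chr1", 200, 300))), 0L)
  expect_error(overlap_pairs(a, a, min_bp = 0), "min_bp")

  a3 <- ps("chr1", c(0, 100, 200), c(50, 150, 250))
  b3 <- ps("chr1", c(10, 110, 210), c(20, 120, 220))
  expect_equal(nrow(overlap_pairs(a3, b3)), 3L)
})

test_that("overlap_pairs is symmetric under argument swap", {
  set.seed(13)
  a <- peak_set(random_intervals(25), label = "a")
  b <- peak_set(random_intervals(25), label = "b")
  ab <- overlap_pairs(a, b)
  ba <- overlap_pairs(b, a)
  key_ab <- sort(paste(ab$a_name, ab$b_name))
  key_ba <- sort(paste(ba$b_name, ba$a_name))
  expect_identical(key_ab, key_ba)
})

test_that("select_top_peaks ranks by score with a deterministic tie-break", {
  x <- ps("chr1", c(0, 100, 200), c(10, 110, 210),
          score = c(0.1, 0.01, 0.5))
  top <- select_top_peaks(x, 2)
  expect_setequal(top$score, c(0.01, 0.1))
  expect_identical(select_top_peaks(x, 10), x)  # n >= size: identity
  # tie at the cutoff: earlier (chrom, start) wins
  y <- ps("chr1", c(0, 100, 200), c(10, 110, 210),
          score = c(0.5, 0.5, 0.1))
  expect_equal(select_top_peaks(y, 2)$start, c(0, 200))
  z <- ps("chr1", 0, 10)
  expect_error(select_top_peaks(z, 1), "score")
})
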