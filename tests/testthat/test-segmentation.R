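test_that("noiseless step and constant sequences segment exactly", {
  w <- mkw(c(rep(0, 200), rep(1, 200)))
  s <- recursive_partition(w)
  expect_equal(nrow(s), 2L)
  expect_equal(s$end[1], 200 * 100)       # breakpoint exactly at window 200
  expect_equal(s$mean_log2, c(0, 1))
  expect_equal(s$n_windows, c(200L, 200L))

  const <- recursive_partition(mkw(rep(0.3, 150)))
  expect_equal(nrow(const), 1L)
  expect_equal(const$n_windows, 150L)

  expect_equal(nrow(recursive_partition(mkw(numeric(0)))), 0L)
})

test_that("segmentation is deterministic and tiles the windowed extent", {
  set.seed(12)
  for (i in 1:4) {
    x <- rep(sample(c(0, 0.58, -1), 3), each = 120) + rnorm(360, 0, 0.1)
    w <- mkw(x)
    s1 <- recursive_partition(w)
    expect_identical(s1, recursive_partition(w))  # determinism
    # disjoint, sorted, covering: starts/ends align with window boundaries
    expect_equal(s1$start[1], w$start[1])
    expect_equal(s1$end[nrow(s1)], w$end[nrow(w)])
    if (nrow(s1) > 1)
      expect_equal(s1$start[-1], s1$end[-nrow(s1)] + 1)
    expect_equal(sum(s1$n_windows), nrow(w))
  }
})

test_that("accepted splits always reduce total SSE", {
  set.seed(13)
  x <- c(rnorm(150, 0, 0.1), rnorm(150, 0.6, 0.1))
  w <- mkw(x)
  s <- recursive_partition(w)
  sse_of <- function(a, b) {
    m <- w$start >= a & w$end <= b
    sum((x[m] - mean(x[m]))^2)
  }
  total <- sum(mapply(sse_of, s$start, s$end))
  expect_lte(total, sum((x - mean(x))^2) + 1e-9)
})

test_that("adjacent-segment merging collapses chains and preserves contrasts", {
  segs <- data.frame(chrom = "1",
                     start = seq(1, by = 1000, length.out = 6),
                     end = seq(1000, by = 1000, length.out = 6),
                     n_windows = 10L,
                     mean_log2 = c(0.01, 0.02, -0.01, 0.015, 0.0, 1.0))
  m <- merge_adjacent(segs, merge_tol = 0.1)
  expect_equal(nrow(m), 2L)               # chain of 5 collapses; 1.0 survives
  expect_equal(m$mean_log2[2], 1.0)
  expect_equal(m$n_windows[1], 50L)
  expect_equal(m$end[1], 5000)

  # neighbors at 0 and 1.0 are untouched
  two <- segs[5:6, ]
  expect_equal(nrow(merge_adjacent(two, 0.1)), 2L)

  # different chromosomes never merge
  segs2 <- segs[1:2, ]; segs2$chrom <- c("1", "2")
  expect_equal(nrow(merge_adjacent(segs2, 0.1)), 2L)

  # merging never increases the segment count (random property)
  set.seed(14)
  for (i in 1:5) {
    k <- sample(3:12, 1)
    s <- data.frame(chrom = "1", start = seq(1, by = 100, length.out = k),
                    end = seq(100, by = 100, length.out = k),
                    n_windows = sample(2:20, k, TRUE),
                    mean_log2 = rnorm(k, 0, 0.2))
    expect_lte(nrow(merge_adjacent(s, 0.1)), k)
  }
})

test_that("CNA classification maps ratios to seg.mean/gmean as documented", {
  segs <- data.frame(chrom = "1", start = 1, end = 100, n_windows = 10L,
                     mean_log2 = log2(c(2, 1, 0.5, 1.5)))
  cl <- classify_cna(segs, call_tol = 0.1)
  # r = 2: two-copy clonal gain -> seg.mean 1.0, gmean 4.0
  expect_equal(cl$seg_mean, c(1, 0, -0.5, 0.5))
  expect_equal(cl$gmean, c(4, 2, 1, 3))
  expect_equal(cl$cna_class, c("gain", "neutral", "loss", "gain"))
  expect_equal(cl$x, 2 * cl$seg_mean)
})

test_that("seg tables round-trip through the writer/reader", {
  segs <- classify_cna(data.frame(chrom = c("1", "1", "X"),
                                  start = c(1, 5001, 1), end = c(5000, 9000, 4000),
                                  n_windows = c(50L, 40L, 40L),
                                  mean_log2 = c(0, 1, -1)), 0.1)
  path <- tempfile(fileext = ".txt")
  write_cna_table(segs, path)
  back <- read_cna_table(path)
  expect_equal(back$seg_mean, segs$seg_mean)
  expect_equal(back$gmean, segs$gmean)
  expect_equal(back$cna_class, segs$cna_class)
  expect_equal(back$start, segs$start)

  # empty segment list -> header-only file
  write_cna_table(segs[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_cna_table(path)), 0L)

  # IGV export carries mean_log2 in its seg.mean column
  igv <- tempfile(fileext = ".seg")
  write_igv_seg(segs, igv, "s1")
  got <- utils::read.delim(igv)
  expect_equal(names(got), c("ID", "chrom", "loc.start", "loc.end",
                             "num.mark", "seg.mean"))
  expect_equal(got$seg.mean, segs$mean_log2)
})
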