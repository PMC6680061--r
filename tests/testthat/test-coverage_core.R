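test_that("events vectors place +1 at block starts and -1 past block ends", {
  b <- tibble::tibble(contig = "chr1", start = c(1L, 2L), len = c(3L, 3L))
  ev <- build_events(b)
  expect_named(ev, "chr1")
  expect_equal(ev$chr1$offset, 1L)
  expect_equal(ev$chr1$deltas, c(1L, 1L, 0L, -1L, -1L))
  expect_equal(sum(ev$chr1$deltas), 0L)
  expect_equal(build_events(b[0, ]), list())
  # extent is offset-restricted, not whole-contig
  b2 <- tibble::tibble(contig = "chr1", start = 500L, len = 10L)
  ev2 <- build_events(b2)[["chr1"]]
  expect_equal(ev2$offset, 500L)
  expect_equal(length(ev2$deltas), 11L)
  # block beyond the contig end is an error naming contig and position
  expect_error(build_events(b2, contig_lengths = c(chr1 = 505L)),
               "chr1:509.*505")
})

test_that("deltas of many random blocks match an independent endpoint tally", {
  set.seed(99)
  n <- 10000
  starts <- sample.int(5000, n, replace = TRUE)
  lens <- sample.int(300, n, replace = TRUE)
  b <- tibble::tibble(contig = "c", start = starts, len = lens)
  ev <- build_events(b)[["c"]]
  # independent tally: count starts and ends per position via table()
  pos <- seq(ev$offset, length.out = length(ev$deltas))
  st <- table(starts)
  en <- table(starts + lens)
  expected <- as.integer(ifelse(is.na(st[as.character(pos)]), 0L,
                                st[as.character(pos)])) -
    as.integer(ifelse(is.na(en[as.character(pos)]), 0L,
                      en[as.character(pos)]))
  expect_equal(ev$deltas, expected)
})

test_that("cumulative sum recovers depth and trims zero flanks", {
  ev <- events_vector("chr1", 1L, c(1L, 1L, 0L, -1L, -1L))
  pc <- events_to_partial(ev)
  expect_equal(pc$values, c(1L, 2L, 2L, 1L))
  expect_equal(pc$start, 1L)
  # leading zeros shift the start
  ev2 <- events_vector("chr1", 10L, c(0L, 0L, 2L, -2L, 0L))
  pc2 <- events_to_partial(ev2)
  expect_equal(pc2$start, 12L)
  expect_equal(pc2$values, 2L)
  # all-zero deltas produce an empty vector
  expect_true(length(events_to_partial(events_vector("c", 1L, c(0L, 0L)))$values) == 0)
  # a negative prefix sum is an internal-consistency error
  expect_error(events_to_partial(events_vector("c", 1L, c(-1L, 1L))),
               "negative prefix")
})

test_that("per-base rendering honors zero handling", {
  pc <- partial_coverage("chr1", 1L, c(1L, 2L, 2L, 1L))
  pb <- to_per_base(pc)
  expect_equal(nrow(pb), 4L)
  expect_equal(pb$start, pb$end)
  pbz <- to_per_base(pc, include_zeros = TRUE, contig_length = 6L)
  expect_equal(nrow(pbz), 6L)
  expect_equal(pbz$coverage, c(1L, 2L, 2L, 1L, 0L, 0L))
})

test_that("blocks merge maximal equal-coverage runs and are lossless", {
  pc <- partial_coverage("chr1", 1L, c(1L, 2L, 2L, 1L))
  bl <- to_blocks(pc)
  expect_equal(bl$start, c(1L, 2L, 4L))
  expect_equal(bl$end, c(1L, 3L, 4L))
  expect_equal(bl$coverage, c(1L, 2L, 1L))
  const <- partial_coverage("chr1", 1L, rep(5L, 100))
  expect_equal(to_blocks(const),
               tibble::tibble(contig = "chr1", start = 1L, end = 100L,
                              coverage = 5L))
  # round-trip: expanding blocks reproduces per-base exactly
  fx <- generate_fixture(fixture_spec(n_reads = 400, seed = 13),
                         tempfile(fileext = ".sam"))
  pb <- compute_coverage(fx$path, "per-base")
  bl2 <- compute_coverage(fx$path, "blocks")
  expanded <- tibble::tibble(
    contig = rep(bl2$contig, bl2$end - bl2$start + 1L),
    pos = unlist(mapply(seq, bl2$start, bl2$end, SIMPLIFY = FALSE)),
    coverage = rep(bl2$coverage, bl2$end - bl2$start + 1L))
  expect_equal(expanded$pos, pb$start)
  expect_equal(expanded$coverage, pb$coverage)
  expect_equal(expanded$contig, pb$contig)
})

test_that("window means tile from position 1 and include zeros", {
  pc <- partial_coverage("chr1", 1L, c(1L, 2L, 2L, 1L, 0L, 0L))
  w <- to_windows(pc, window = 2, contig_length = 6)
  expect_equal(w$coverage, c(1.5, 1.5, 0.0))
  expect_equal(w$start, c(1L, 3L, 5L))
  expect_equal(w$end, c(2L, 4L, 6L))
  # degenerate tiling: one window spanning the contig
  w1 <- to_windows(pc, window = 6, contig_length = 6)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$coverage, sum(pc$values) / 6)
  # short terminal window has a mean over its actual length
  set.seed(5)
  vals <- sample(0:4, 100, replace = TRUE)
  pcr <- partial_coverage("chr1", 1L, as.integer(vals))
  w7 <- to_windows(pcr, window = 7, contig_length = 100)
  expect_equal(nrow(w7), 15L)
  expect_equal(w7$end[15] - w7$start[15] + 1L, 2L)
  expect_equal(w7$coverage,
               as.numeric(tapply(vals, (seq_len(100) - 1) %/% 7, mean)),
               ignore_attr = TRUE)
  expect_error(to_windows(pcr, window = 0, contig_length = 100), "window")
})

test_that("coverage mass is conserved from alignment blocks to output", {
  fx <- generate_fixture(fixture_spec(n_reads = 600, seed = 23),
                         tempfile(fileext = ".sam"))
  pb <- compute_coverage(fx$path, "per-base")
  expect_equal(sum(pb$coverage), truth_mass(fx$reads))
  w <- compute_coverage(fx$path, "windows", window = 250)
  expect_equal(sum(w$coverage * (w$end - w$start + 1L)), sum(pb$coverage))
})

test_that("counter width reflects compact range and promotes checked", {
  expect_equal(partial_coverage("c", 1L, c(5L, 65535L))$width, "short")
  expect_equal(partial_coverage("c", 1L, c(5L, 65536L))$width, "int")
  # promotion past the 32-bit range never wraps
  ev <- events_vector("c", 1L, c(2000000000L, 2000000000L,
                                 -2000000000L, -2000000000L))
  pc <- events_to_partial(ev)
  expect_equal(pc$values[2], 4e9, tolerance = 0)
  expect_equal(pc$width, "numeric")
})
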