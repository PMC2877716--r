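make_track <- function(chrom, pos, sample = "WT") {
  tf <- tempfile(fileext = ".bed")
  if (length(pos)) {
    writeLines(sprintf("%s\t%d\t%d\t.\t.\t+", chrom, pos, pos + 35L), tf)
  } else writeLines(character(0), tf)
  read_tags(tf, sample)
}

small_ann <- function(len = 5000L, mask = NULL) {
  sizes <- write_chrom_sizes(c(chr1 = len), tempfile())
  mask_path <- NULL
  if (!is.null(mask))
    mask_path <- write_bed(data.frame("chr1", mask$start, mask$end),
                           tempfile())
  read_annotation(sizes, mask_path = mask_path)
}

test_that("window counting matches a brute-force enumeration", {
  ann <- small_ann(3000L)
  spec <- window_spec(240, 10)
  wt <- make_track("chr1", c(100L))
  ko <- make_track("chr1", integer(0), "KO")
  w <- count_windows(wt, ko, ann, spec)
  # brute force: windows with start <= 100 < start + 240, starts multiples of 10
  brute <- sum(vapply(w$start, function(s) 100 >= s && 100 < s + 240,
                      logical(1)))
  expect_equal(sum(w$R), brute)
  expect_equal(sum(w$R == 1), 11L)  # starts 0, 10, ..., 100
  expect_true(all(w$N == 0))
  expect_equal(w$D, w$R - w$N)
  # window grid: starts at multiples of step, last full window kept
  expect_equal(w$start[1], 0L)
  expect_equal(max(w$end), 3000L)
})

test_that("window counting half-open boundary and empty input", {
  ann <- small_ann(1000L)
  wt <- make_track("chr1", c(5L, 239L, 240L))
  ko <- make_track("chr1", integer(0), "KO")
  w <- count_windows(wt, ko, ann, window_spec(240, 240))
  expect_equal(w$R[w$start == 0], 2L)   # 240 excluded from [0, 240)
  expect_equal(w$R[w$start == 240], 1L)
  w0 <- count_windows(make_track("chr1", integer(0)),
                      make_track("chr1", integer(0), "KO"), ann)
  expect_true(all(w0$R == 0 & w0$N == 0 & w0$D == 0))
  expect_error(
    count_windows(make_track("chrZ", 10L), ko, ann),
    "chrZ")
})

test_that("masked windows are excluded and never called", {
  ann <- small_ann(2000L, mask = data.frame(start = 500L, end = 510L))
  wt <- make_track("chr1", rep(600L, 50))  # huge D nearby
  ko <- make_track("chr1", integer(0), "KO")
  w <- count_windows(wt, ko, ann, window_spec(240, 10))
  # windows overlapping [500, 510) by >= 1 bp are excluded
  overlapping <- w$start < 510 & w$start + 240 > 500
  expect_true(all(w$excluded[overlapping]))
  expect_false(any(w$excluded[!overlapping]))
  called <- call_significant(w, d0 = 6)
  expect_false(any(called$significant & called$excluded))
})

test_that("significance calling thresholds at d0 with mask precedence", {
  w <- data.frame(chrom = "chr1", start = c(0, 10, 20), end = c(240, 250, 260),
                  R = c(5L, 6L, 50L), N = 0L, D = c(5L, 6L, 50L),
                  excluded = c(FALSE, FALSE, TRUE))
  called <- call_significant(w, d0 = 6)
  expect_equal(called$significant, c(FALSE, TRUE, FALSE))
  # a model without d0 demands an explicit threshold
  null <- skellam_null(0.2, 0.2)
  m <- fit_locfdr(data.frame(d = -2:2, count = c(1, 5, 10, 5, 1) * 100),
                  null, p0 = 1)
  expect_true(is.na(m$d0))
  expect_error(call_significant(w, m), "explicit d0")
})

test_that("identical WT and KO tracks produce zero peaks end to end", {
  ann <- small_ann(5000L)
  pos <- sort(sample.int(4500L, 200))
  wt <- make_track("chr1", pos)
  ko <- make_track("chr1", pos, "KO")
  w <- count_windows(wt, ko, ann, window_spec(240, 10))
  expect_true(all(w$D == 0))
  called <- call_significant(w, d0 = 6)
  expect_equal(nrow(assemble_peaks(called, window_spec(240, 10))), 0L)
})

test_that("peak assembly unions step-bins of significant windows", {
  spec <- window_spec(240, 10)
  w <- data.frame(chrom = "chr1",
                  start = c(100L, 110L, 120L, 200L, 400L),
                  end = c(340L, 350L, 360L, 440L, 640L),
                  R = 9L, N = 0L, D = c(9L, 8L, 9L, 7L, 6L),
                  excluded = FALSE, significant = c(TRUE, TRUE, TRUE, TRUE,
                                                    FALSE))
  p <- assemble_peaks(w, spec)
  expect_equal(p$start, c(100L, 200L))
  expect_equal(p$end, c(130L, 210L))      # 10 bp minimum footprint
  expect_equal(p$n_windows, c(3L, 1L))
  expect_equal(p$max_d, c(9, 7))
  # single significant window -> one step-sized peak
  w1 <- w[4, ]
  p1 <- assemble_peaks(w1, spec)
  expect_equal(p1$end - p1$start, 10L)
})

test_that("close-peak merging applies the gap rule and is idempotent", {
  p <- data.frame(chrom = "chr1", start = c(0L, 120L), end = c(50L, 180L))
  m <- merge_close_peaks(p, 100)
  expect_equal(nrow(m), 1L)               # gap 70 <= 100
  expect_equal(c(m$start, m$end), c(0L, 180L))
  p2 <- data.frame(chrom = "chr1", start = c(0L, 151L), end = c(50L, 180L))
  expect_equal(nrow(merge_close_peaks(p2, 100)), 2L)  # gap 101: unmerged
  # boundary: gap exactly 100 merges
  p3 <- data.frame(chrom = "chr1", start = c(0L, 150L), end = c(50L, 180L))
  expect_equal(nrow(merge_close_peaks(p3, 100)), 1L)
  # idempotence on random fixtures
  set.seed(13)
  for (rep in 1:20) {
    ps <- rand_peak_set(30)
    m1 <- merge_close_peaks(ps, 100)
    expect_identical(merge_close_peaks(m1, 100), m1)
  }
})

test_that("short-peak filtering uses the <= 20 bp rule", {
  p <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L, 300L),
                  end = c(10L, 120L, 221L, 540L))
  f <- filter_short(p, 20)
  expect_equal(f$kept$end - f$kept$start, c(21L, 240L))
  expect_equal(f$too_short$end - f$too_short$start, c(10L, 20L))
  # empty input passes through
  f0 <- filter_short(p[0, ], 20)
  expect_equal(nrow(f0$kept), 0L)
})

test_that("planted enriched regions are recovered as peaks", {
  set.seed(17)
  starts <- c(5000L, 20000L, 40000L, 60000L, 80000L)
  plants <- data.frame(start = starts, end = starts + 200L)
  sim <- gen_genome_and_tags(100000L, peaks = plants, pwm = "AAAGCGAGGC",
                             enrichment = 30L, seed = 171)
  ann <- read_annotation(sim$chrom_sizes)
  wt <- read_tags(sim$wt, "WT", ann)
  ko <- read_tags(sim$ko, "KO", ann)
  w <- count_windows(wt, ko, ann, window_spec(240, 10))
  called <- call_significant(w, d0 = 6)
  peaks <- merge_close_peaks(assemble_peaks(called, window_spec(240, 10)), 100)
  hit <- vapply(seq_len(nrow(plants)), function(i) {
    any(peaks$start < plants$end[i] & peaks$end > plants$start[i])
  }, logical(1))
  expect_true(all(hit))
})
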