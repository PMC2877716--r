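# Independent oracles and small fixture builders used across the suite.

# Skellam pmf by truncated convolution of two Poissons:
# P(D = d) = sum_k Pois(lambda_r, d + k) * Pois(lambda_n, k)
conv_pmf <- function(d, lambda_r, lambda_n, kmax = 400L) {
  k <- 0:kmax
  vapply(d, function(di) sum(stats::dpois(di + k, lambda_r) *
                               stats::dpois(k, lambda_n)), numeric(1))
}

conv_sf <- function(d, lambda_r, lambda_n, dmax = 400L) {
  vapply(d, function(di) sum(conv_pmf(di:dmax, lambda_r, lambda_n)),
         numeric(1))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a quick BED file of tag intervals (0-based half-open)
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), sizes), path)
  path
}

# substitute one base at a 1-based position, choosing a different base
mutate_at <- function(site, pos, to = NULL) {
  v <- strsplit(site, "")[[1]]
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), v[pos])[1]
  v[pos] <- to
  paste(v, collapse = "")
}

# random non-overlapping peak set on one chromosome
rand_peak_set <- function(n, chrom_len = 100000L) {
  starts <- sort(sample.int(chrom_len - 500L, n))
  widths <- sample(10:300, n, replace = TRUE)
  ends <- pmin(starts + widths, chrom_len)
  keep <- c(TRUE, starts[-1] >= ends[-n])
  data.frame(chrom = "chr1", start = starts, end = ends)[keep, , drop = FALSE]
}

# Synthetic stand-in for a published-style peak/motif supplementary table:
# n_total peaks of which n_short are too short to search; among the analyzed
# remainder, specified numbers of High/Medium/Low motif sites (single-base
# variants of the reference site) and the rest flagged "none". Analyzed
# region lengths are chosen to hit mean_len exactly.
synthetic_peak_motif_table <- function(n_total = 176L, n_short = 32L,
                                       n_high = 62L, n_med = 27L,
                                       n_low = 49L, mean_len = 112L,
                                       reference = "AAAGCGAGGC") {
  n_analyzed <- n_total - n_short
  n_none <- n_analyzed - n_high - n_med - n_low
  stopifnot(n_none >= 0L)
  high <- c(reference,
            vapply(rep(c(2L, 4L, 5L), length.out = n_high - 1L),
                   function(p) mutate_at(reference, p), character(1)))
  med <- vapply(rep(c(1L, 9L, 10L), length.out = n_med),
                function(p) mutate_at(reference, p), character(1))
  low <- vapply(rep(c(3L, 6L, 7L, 8L), length.out = n_low),
                function(p) mutate_at(reference, p), character(1))
  motifs <- c(high, med, low, rep("none", n_none))
  # analyzed lengths: all but one at 110, the last absorbs the remainder
  lens <- rep(110L, n_analyzed)
  lens[n_analyzed] <- mean_len * n_analyzed - sum(lens[-n_analyzed])
  short_lens <- sample(10:20, n_short, replace = TRUE)
  starts <- cumsum(c(0L, rep(1000L, n_total - 1L)))
  all_lens <- c(lens, short_lens)
  peak_table(chrom = "chr1", start = starts, end = starts + all_lens,
             gene = "", motif = c(motifs, rep("too short", n_short)),
             affinity = "")
}
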