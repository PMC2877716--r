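#' Signed distance from each peak center to the nearest TSS
#'
#' The peak center is `floor((start+end)/2)`; the nearest TSS is chosen by
#' absolute distance. The sign follows the gene's strand: negative means the
#' peak center lies upstream of the TSS (5' of the gene), positive
#' downstream. Absolute-distance ties prefer the TSS that lies upstream of
#' the peak (positive signed distance), then the lexicographically smaller
#' gene symbol.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`.
#' @param annotation a [read_annotation()] object with TSS records.
#' @return data.frame with columns `peak` (row index), `gene`, `distance`,
#'   `within_1kb`, `within_10kb`; `gene` is `NA` and distances `NA` for
#'   peaks on chromosomes without any TSS.
#' @export
nearest_tss <- function(peaks, annotation) {
  tss <- annotation$tss
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    center <- (peaks$start[i] + peaks$end[i]) %/% 2L
    cand <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L)
      return(data.frame(peak = i, gene = NA_character_,
                        distance = NA_integer_, within_1kb = NA,
                        within_10kb = NA))
    cand$signed <- ifelse(cand$strand == "+", center - cand$pos,
                          cand$pos - center)
    # TSS upstream of the peak on the gene's strand <=> signed distance > 0
    cand <- cand[order(abs(cand$signed), -sign(cand$signed), cand$gene),
                 , drop = FALSE]
    d <- cand$signed[1]
    data.frame(peak = i, gene = cand$gene[1], distance = as.integer(d),
               within_1kb = abs(d) <= 1000L, within_10kb = abs(d) <= 10000L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positional histogram of peak-to-TSS distances
#'
#' Tallies signed distances into fixed-width bins over a symmetric window
#' around the TSS, half-open `[lo, hi)` per bin.
#'
#' @param distances integer vector of signed distances (bp), or the output
#'   of [nearest_tss()].
#' @param bin bin width in bp (default 100).
#' @param range half-range in bp (default 1000: bins span `[-1000, 1000)`).
#' @return data.frame with `lo`, `hi`, `count`.
#' @export
positional_histogram <- function(distances, bin = 100L, range = 1000L) {
  if (is.data.frame(distances)) distances <- distances$distance
  distances <- distances[!is.na(distances)]
  if (range %% bin != 0L) stop("bin width must divide the range")
  breaks <- seq.int(-range, range, by = bin)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  inside <- distances >= -range & distances < range
  idx <- (distances[inside] + range) %/% bin + 1L
  data.frame(lo = lo, hi = hi,
             count = tabulate(idx, nbins = length(lo)))
}

#' Tally peaks within 1 kB and 10 kB of a TSS
#'
#' Inclusive boundaries (`|distance| <= 1000` / `<= 10000`); the 1 kB set is
#' by construction a subset of the 10 kB set.
#'
#' @param distances integer vector of signed distances, or [nearest_tss()]
#'   output.
#' @return list with `n`, `within_10kb`, `within_1kb`.
#' @export
proximity_tally <- function(distances) {
  if (is.data.frame(distances)) distances <- distances$distance
  d <- abs(distances[!is.na(distances)])
  list(n = length(distances),
       within_10kb = sum(d <= 10000L),
       within_1kb = sum(d <= 1000L))
}
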