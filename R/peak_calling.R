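#' Sliding-window specification
#'
#' Windows of `width` bp are placed every `step` bp from position 0 on each
#' chromosome; a final partial window at the chromosome end is dropped.
#'
#' @param width window width in bp (default 240).
#' @param step step between window starts in bp (default 10).
#' @return a `window_spec` list.
#' @export
window_spec <- function(width = 240L, step = 10L) {
  width <- as.integer(width); step <- as.integer(step)
  stopifnot(width > 0L, step > 0L, step <= width)
  structure(list(width = width, step = step), class = "window_spec")
}

# number of sorted positions falling in [start, start+width)
.count_in_windows <- function(pos, starts, width) {
  if (length(pos) == 0L)
    return(integer(length(starts)))
  pos <- sort(pos)
  hi <- findInterval(starts + width - 0.5, pos)
  lo <- findInterval(starts - 0.5, pos)
  as.integer(hi - lo)
}

#' Count WT and KO tags in sliding windows
#'
#' For every window the wild-type count `R`, knockout count `N` and the
#' difference statistic `D = R - N` are recorded. A tag is counted when its
#' 5' position lies in `[start, start + width)`. Windows overlapping a
#' repeat-masked base by at least 1 bp are flagged `excluded` and carry no
#' weight in any downstream statistic.
#'
#' @param wt,ko `tag_track` objects from [read_tags()].
#' @param annotation a [read_annotation()] object (chromosome sizes + mask).
#' @param spec a [window_spec()].
#' @return data.frame with columns `chrom`, `start`, `end`, `R`, `N`, `D`,
#'   `excluded`.
#' @export
count_windows <- function(wt, ko, annotation, spec = window_spec()) {
  sizes <- annotation$chrom_sizes
  for (tr in list(wt, ko)) {
    unknown <- setdiff(unique(tr$chrom), names(sizes))
    if (length(unknown))
      stop("chromosome(s) in tags but not in chromosome sizes: ",
           paste(unknown, collapse = ", "))
  }
  out <- lapply(names(sizes), function(chr) {
    len <- sizes[[chr]]
    if (len < spec$width) return(NULL)
    starts <- seq.int(0L, len - spec$width, by = spec$step)
    R <- .count_in_windows(wt$pos[wt$chrom == chr], starts, spec$width)
    N <- .count_in_windows(ko$pos[ko$chrom == chr], starts, spec$width)
    msk <- annotation$mask[annotation$mask$chrom == chr, , drop = FALSE]
    excluded <- if (nrow(msk)) {
      win_ir <- IRanges::IRanges(starts + 1L, starts + spec$width)
      mask_ir <- IRanges::IRanges(msk$start + 1L, msk$end)
      IRanges::overlapsAny(win_ir, mask_ir)
    } else rep(FALSE, length(starts))
    data.frame(chrom = chr, start = starts,
               end = starts + spec$width, R = R, N = N, D = R - N,
               excluded = excluded)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag significant windows at the critical difference
#'
#' A window is significant iff it is not excluded and `D >= d0`, where `d0`
#' comes from the fitted locFDR model (or an explicit override).
#'
#' @param windows data.frame from [count_windows()].
#' @param model a [fit_locfdr()] model, or `NULL` when `d0` is given.
#' @param d0 explicit integer threshold overriding the model's.
#' @return `windows` with an added logical `significant` column.
#' @export
call_significant <- function(windows, model = NULL, d0 = NULL) {
  if (is.null(d0)) {
    if (is.null(model) || is.na(model$d0))
      stop("the fitted model has no defined critical difference; ",
           "supply an explicit d0")
    d0 <- model$d0
  }
  d0 <- as.integer(d0)
  windows$significant <- !windows$excluded & windows$D >= d0
  windows
}

#' Assemble significant windows into peaks
#'
#' Each significant window contributes its step-bin `[start, start + step)`;
#' adjacent or overlapping contributed bins are unioned into peaks. This
#' footprint makes the minimum possible peak length equal to the step size.
#'
#' @param windows output of [call_significant()].
#' @param spec the [window_spec()] used for counting.
#' @return data.frame with columns `chrom`, `start`, `end`, `n_windows`
#'   (supporting windows) and `max_d`.
#' @export
assemble_peaks <- function(windows, spec = window_spec()) {
  sig <- windows[windows$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      max_d = integer(0)))
  parts <- lapply(split(sig, sig$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    ir <- IRanges::IRanges(s$start + 1L, s$start + spec$step)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    rev <- S4Vectors::mcols(red)$revmap
    data.frame(chrom = s$chrom[1],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               n_windows = lengths(rev),
               max_d = vapply(rev, function(i) max(s$D[i]), numeric(1)))
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge peaks that lie close together
#'
#' Bound regions separated by at most `max_gap` bp are expanded into one
#' larger region (positioning noise makes nearby fragments one binding
#' event). Idempotent.
#'
#' @param peaks data.frame from [assemble_peaks()].
#' @param max_gap maximum inter-peak gap in bp that still merges
#'   (default 100).
#' @return merged peaks in the same format.
#' @export
merge_close_peaks <- function(peaks, max_gap = 100L) {
  if (nrow(peaks) == 0L) return(peaks)
  has_meta <- all(c("n_windows", "max_d") %in% names(peaks))
  parts <- lapply(split(peaks, peaks$chrom), function(p) {
    p <- p[order(p$start), , drop = FALSE]
    ir <- IRanges::IRanges(p$start + 1L, p$end)
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L,
                           with.revmap = TRUE)
    rev <- S4Vectors::mcols(red)$revmap
    out <- data.frame(chrom = p$chrom[1],
                      start = IRanges::start(red) - 1L,
                      end = IRanges::end(red))
    if (has_meta) {
      out$n_windows <- vapply(rev, function(i) sum(p$n_windows[i]), numeric(1))
      out$max_d <- vapply(rev, function(i) max(p$max_d[i]), numeric(1))
    }
    out
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard very short peaks
#'
#' Regions of `min_exclusive` bp or shorter are too short to search
#' meaningfully for 10-15 bp motifs and are set aside (they are retained in
#' the `too_short` element so output tables can flag them).
#'
#' @param peaks data.frame of peaks.
#' @param min_exclusive peaks with length <= this are discarded (default 20).
#' @return list with elements `kept` and `too_short`.
#' @export
filter_short <- function(peaks, min_exclusive = 20L) {
  len <- peaks$end - peaks$start
  list(kept = peaks[len > min_exclusive, , drop = FALSE],
       too_short = peaks[len <= min_exclusive, , drop = FALSE])
}
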