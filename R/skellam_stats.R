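#' Skellam null distribution for per-window read-count differences
#'
#' Constructs the null model for the statistic `D = R - N`, the difference in
#' read counts between a wild-type pulldown and a knockout negative-control
#' pulldown in one genomic window. When both per-window counts are Poisson
#' with rates `lambda_r` and `lambda_n`, their difference follows a Skellam
#' distribution; unequal sequencing depths simply shift the mode of the null.
#'
#' @param lambda_r expected wild-type read count per window (>= 0).
#' @param lambda_n expected knockout read count per window (>= 0).
#' @return an object of class `skellam_null`.
#' @examples
#' null <- skellam_null(0.15273, 0.21607)
#' skellam_pmf(0, null)
#' @export
skellam_null <- function(lambda_r, lambda_n) {
  stopifnot(is.numeric(lambda_r), is.numeric(lambda_n),
            length(lambda_r) == 1L, length(lambda_n) == 1L,
            is.finite(lambda_r), is.finite(lambda_n))
  if (lambda_r < 0 || lambda_n < 0)
    stop("Poisson rates must be non-negative")
  structure(list(lambda_r = lambda_r, lambda_n = lambda_n),
            class = "skellam_null")
}

#' @export
print.skellam_null <- function(x, ...) {
  cat(sprintf("Skellam null: lambda_R = %g, lambda_N = %g (mode shift %g)\n",
              x$lambda_r, x$lambda_n, x$lambda_r - x$lambda_n))
  invisible(x)
}

# log I_nu(x) for integer nu >= 0 by direct series summation in log space.
# Robust where besselI() underflows (small x, large nu); terms
# t_k = (x/2)^(2k+nu) / (k! (nu+k)!) are summed with a log-sum-exp.
log_bessel_i <- function(nu, x) {
  stopifnot(nu >= 0, x >= 0)
  if (x == 0) return(if (nu == 0) 0 else -Inf)
  k <- 0:200
  logt <- (2 * k + nu) * log(x / 2) - lgamma(k + 1) - lgamma(nu + k + 1)
  m <- max(logt)
  m + log(sum(exp(logt - m)))
}

#' Skellam probability mass function
#'
#' `P(D = d)` under the Skellam null: `exp(-(lR+lN)) * (lR/lN)^(d/2) *
#' I_d(2*sqrt(lR*lN))`, with `I_d` the modified Bessel function of the first
#' kind of order `d`. Evaluated in log space so that extreme tails do not
#' underflow. When one rate is zero the distribution degenerates to a
#' (possibly sign-flipped) Poisson; when both are zero it is a point mass at
#' zero.
#'
#' @param d integer vector of count differences.
#' @param null a [skellam_null()] object.
#' @return vector of probabilities.
#' @export
skellam_pmf <- function(d, null) {
  stopifnot(inherits(null, "skellam_null"))
  d <- as.integer(round(d))
  lr <- null$lambda_r
  ln <- null$lambda_n
  if (lr == 0 && ln == 0) return(as.numeric(d == 0L))
  if (ln == 0) return(ifelse(d >= 0L, stats::dpois(pmax(d, 0L), lr), 0))
  if (lr == 0) return(ifelse(d <= 0L, stats::dpois(pmax(-d, 0L), ln), 0))
  x <- 2 * sqrt(lr * ln)
  vapply(d, function(di) {
    logp <- -(lr + ln) + (di / 2) * log(lr / ln) + log_bessel_i(abs(di), x)
    exp(logp)
  }, numeric(1))
}

#' Skellam upper-tail probability
#'
#' `P(D >= d)` under the null; the survival function feeding the tail false
#' discovery rate. The sum is truncated where the remaining Poisson-bounded
#' mass drops below 1e-16 (`P(D >= x) <= P(R >= x)`).
#'
#' @inheritParams skellam_pmf
#' @return vector of upper-tail probabilities.
#' @export
skellam_sf <- function(d, null) {
  stopifnot(inherits(null, "skellam_null"))
  d <- as.integer(round(d))
  lr <- null$lambda_r
  ln <- null$lambda_n
  # upper truncation point: beyond it P(D >= x) <= P(R >= x) < 1e-16
  hi <- if (lr > 0) stats::qpois(1e-16, lr, lower.tail = FALSE) + 2L else 1L
  lo_all <- min(c(d, 0L))
  # lower truncation for the complement sum
  lo <- if (ln > 0) -(stats::qpois(1e-16, ln, lower.tail = FALSE) + 2L) else -1L
  lo <- min(lo, lo_all)
  support <- lo:hi
  pm <- skellam_pmf(support, null)
  cum_upper <- rev(cumsum(rev(pm)))   # P(D >= support[i]) within truncation
  vapply(d, function(di) {
    if (di <= lo) return(1)
    if (di > hi) return(0)
    min(1, cum_upper[di - lo + 1L])
  }, numeric(1))
}

#' Estimate a per-window Poisson rate from observed window counts
#'
#' @param counts integer vector of per-window read counts (non-excluded
#'   windows only).
#' @param method `"mean"` (default): arithmetic mean over all windows.
#'   `"null_fit"`: mean over windows with count <= 3, damping the influence of
#'   true signal windows on the background rate.
#' @return estimated rate per window.
#' @export
estimate_lambda <- function(counts, method = c("mean", "null_fit")) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("cannot estimate a rate from zero windows")
  if (anyNA(counts) || any(counts < 0)) stop("window counts must be non-negative")
  if (method == "null_fit") {
    counts <- counts[counts <= 3]
    if (length(counts) == 0L) stop("no windows with count <= 3 for null_fit")
  }
  mean(counts)
}

# Normalize the d input of fit_locfdr to an integer-bin histogram covering
# the full observed range, with a 0.5 pseudo-count for empty interior bins.
.d_histogram <- function(d) {
  if (is.data.frame(d)) {
    stopifnot(all(c("d", "count") %in% names(d)))
    dv <- as.integer(d$d)
    ct <- as.numeric(d$count)
    if (any(ct < 0)) stop("histogram counts must be non-negative")
    o <- order(dv)
    dv <- dv[o]; ct <- ct[o]
    if (anyDuplicated(dv)) stop("duplicate d bins in histogram")
  } else {
    d <- as.integer(d)
    if (length(d) == 0L) stop("empty histogram")
    tb <- table(d)
    dv <- as.integer(names(tb))
    ct <- as.numeric(tb)
  }
  if (length(dv) == 0L || sum(ct) <= 0) stop("empty histogram")
  full <- min(dv):max(dv)
  counts <- numeric(length(full))
  counts[match(dv, full)] <- ct
  list(d = full, count = counts, n = sum(ct))
}

#' Fit the local false discovery rate mixture over window differences
#'
#' Models the observed density of `D` as the two-component mixture
#' `f(D) = p0 * f0(D) + p1 * f1(D)` with `f0` the Skellam null and `f1` the
#' (implicit) signal density. The local fdr at each integer `d` is
#' `clip(p0 * f0(d) / fhat(d), 0, 1)`, where `fhat` is the empirical histogram
#' density (empty interior bins receive a 0.5 pseudo-count so the fdr is
#' defined at every d up to the observed maximum). For `d >= 1` a
#' running-minimum regularization enforces a non-increasing fdr, and the
#' critical difference `d0` is the smallest `d >= 1` whose regularized fdr
#' falls to or below the threshold `f_p`.
#'
#' @param d either an integer vector of observed window differences, or a
#'   data.frame histogram with columns `d` and `count`.
#' @param null a [skellam_null()] object (`f0`).
#' @param p0 null-component weight in `[0,1]`, or `"auto"` for central
#'   matching: `p0 = min(1, min over d in [-2,2] of fhat(d)/f0(d))`.
#' @param f_p local fdr threshold (default 0.01).
#' @return an object of class `locfdr_model` with elements `table`
#'   (d, count, fhat, f0, fdr_raw, fdr), `p0`, `f_p`, `d0` (integer or `NA`),
#'   `null`, and `n_windows`.
#' @export
fit_locfdr <- function(d, null, p0 = "auto", f_p = 0.01) {
  stopifnot(inherits(null, "skellam_null"))
  if (!is.numeric(f_p) || length(f_p) != 1L || f_p <= 0 || f_p >= 1)
    stop("f_p must lie in (0, 1)")
  h <- .d_histogram(d)
  fhat <- (h$count + 0.5 * (h$count == 0)) / h$n
  f0 <- skellam_pmf(h$d, null)

  if (identical(p0, "auto")) {
    central <- h$d >= -2L & h$d <= 2L & f0 > 0
    if (!any(central))
      stop("no observed d in [-2, 2]; supply p0 explicitly")
    p0 <- min(1, min(fhat[central] / f0[central]))
  }
  stopifnot(is.numeric(p0), length(p0) == 1L, p0 >= 0, p0 <= 1)

  fdr_raw <- pmin(1, pmax(0, p0 * f0 / fhat))
  fdr <- fdr_raw
  pos <- which(h$d >= 1L)
  if (length(pos)) fdr[pos] <- cummin(fdr_raw[pos])

  hit <- pos[fdr[pos] <= f_p]
  d0 <- if (length(hit)) h$d[min(hit)] else NA_integer_

  structure(list(
    table = data.frame(d = h$d, count = h$count, fhat = fhat, f0 = f0,
                       fdr_raw = fdr_raw, fdr = fdr),
    p0 = p0, f_p = f_p, d0 = d0, null = null, n_windows = h$n
  ), class = "locfdr_model")
}

#' @export
print.locfdr_model <- function(x, ...) {
  cat(sprintf("locFDR model over %g windows: p0 = %.6g, f_p = %g, d0 = %s\n",
              x$n_windows, x$p0, x$f_p,
              if (is.na(x$d0)) "none" else x$d0))
  invisible(x)
}

#' Tail (set-level) false discovery rate at a cutoff
#'
#' `FDR(d) = p0 * P0(D >= d) / Phat(D >= d)`, the expected fraction of null
#' windows among all windows called at cutoff `d`. Both tails are evaluated
#' over the observed histogram range, which makes the value equal to the
#' `fhat`-weighted mean of the unregularized local fdr over `{D >= d}` when no
#' clipping occurred.
#'
#' @param model a [fit_locfdr()] model.
#' @param d integer cutoff; must not lie left of the observed range.
#' @return value in `[0,1]`, or `NA` if the empirical tail mass is zero.
#' @export
tail_fdr <- function(model, d) {
  stopifnot(inherits(model, "locfdr_model"), length(d) == 1L)
  d <- as.integer(round(d))
  tab <- model$table
  if (d < min(tab$d)) stop("cutoff lies left of the observed range")
  sel <- tab$d >= d
  tail_hat <- sum(tab$fhat[sel])
  if (tail_hat <= 0) return(NA_real_)
  tail_null <- sum(tab$f0[sel])
  min(1, max(0, model$p0 * tail_null / tail_hat))
}
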