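#' Reference-normalized relative expression scaled to the WT group
#'
#' Each sample's target measurement is divided by its reference (e.g. Gapdh)
#' measurement as a control for sample handling, and all ratios are then
#' scaled so that the wild-type group mean equals 1. A value of 1 for the KO
#' group therefore indicates no difference from WT.
#'
#' @param samples data.frame with columns `genotype` (`WT`/`KO`), `target`
#'   and `reference` (see [read_expression_table()]).
#' @param ct_scale if `TRUE`, `target` and `reference` are qPCR cycle
#'   thresholds and the per-sample ratio is `2^-(target - reference)`
#'   (the delta-Ct transform); default `FALSE` treats them as linear-scale
#'   abundances.
#' @return `samples` with an added `relative` column.
#' @export
relative_expression <- function(samples, ct_scale = FALSE) {
  stopifnot(all(c("genotype", "target", "reference") %in% names(samples)))
  if (!any(samples$genotype == "WT")) stop("need at least one WT sample")
  if (!ct_scale && any(samples$reference == 0))
    stop("reference measurements must be nonzero")
  ratio <- if (ct_scale) 2^-(samples$target - samples$reference)
  else samples$target / samples$reference
  samples$relative <- ratio / mean(ratio[samples$genotype == "WT"])
  samples
}

#' Two-tailed unpaired Student's t-test between genotype groups
#'
#' Equal-variance (pooled) two-sample t-test with `n1 + n2 - 2` degrees of
#' freedom, the standard test for two-group qPCR comparisons.
#'
#' @param wt,ko numeric vectors of per-animal values (>= 2 each).
#' @return list with `t`, `df`, `p`.
#' @export
group_ttest <- function(wt, ko) {
  if (length(wt) < 2L || length(ko) < 2L)
    stop("each group needs at least 2 values")
  res <- stats::t.test(wt, ko, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
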