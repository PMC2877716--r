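#' A binding-site-selection (SELEX) oligo pool
#'
#' One round of an in vitro selection: a pool of oligos each carrying a
#' random insert between fixed flanking sequences (the PCR handles of the
#' screen).
#'
#' @param sequences character vector of insert sequences.
#' @param round selection round number (0 = unselected starting pool).
#' @param flank_5p,flank_3p fixed flanking sequences (may be empty).
#' @return a `selex_pool` list.
#' @export
selex_pool <- function(sequences, round, flank_5p = "", flank_3p = "") {
  stopifnot(length(sequences) >= 1L, round >= 0L)
  structure(list(sequences = toupper(sequences), round = as.integer(round),
                 flank_5p = toupper(flank_5p), flank_3p = toupper(flank_3p)),
            class = "selex_pool")
}

.pool_context <- function(pool, include_flanks = TRUE) {
  if (include_flanks)
    paste0(pool$flank_5p, pool$sequences, pool$flank_3p)
  else pool$sequences
}

#' Consensus motif from a selected oligo pool
#'
#' Runs the ZOOPS Gibbs sampler over the final-round pool to extract the
#' fixed-width consensus that selection has enriched. The search spans
#' insert plus flanks by default, because a selected motif frequently
#' straddles the junction between the random insert and a flanking
#' sequence.
#'
#' @param pool a [selex_pool()] (typically the last round), or a plain
#'   character vector of sequences.
#' @param width consensus width in bp (default 12).
#' @param include_flanks search insert+flank context (default TRUE).
#' @param ... further arguments to [gibbs_search()] (`trials`, `iterations`,
#'   `seed`, ...).
#' @return a `motif_model` with IUPAC consensus.
#' @export
selex_consensus <- function(pool, width = 12L, include_flanks = TRUE, ...) {
  seqs <- if (inherits(pool, "selex_pool")) {
    .pool_context(pool, include_flanks)
  } else as.character(pool)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (all(nchar(seqs) < width))
    stop("consensus width exceeds every sequence length")
  gibbs_search(seqs, width = width, ...)
}

#' Per-round mean best-site log-odds of a PWM across selection rounds
#'
#' Quantifies progressive enrichment: for each round, the mean over pool
#' members of the best-site log-odds of `model` in the insert+flank context.
#' On a positively selected simulation the trace is non-decreasing; on an
#' unselected pool it sits at the background expectation.
#'
#' @param pools list of [selex_pool()] objects (>= 2 rounds).
#' @param model a `motif_model` to score with.
#' @param include_flanks score insert+flank context (default TRUE).
#' @return data.frame with columns `round` and `mean_logodds`.
#' @export
enrichment_trace <- function(pools, model, include_flanks = TRUE) {
  if (length(pools) < 2L) stop("need at least 2 rounds")
  rows <- lapply(pools, function(p) {
    stopifnot(inherits(p, "selex_pool"))
    seqs <- .pool_context(p, include_flanks)
    if (length(seqs) == 0L) stop("empty pool in round ", p$round)
    lo <- vapply(seqs, function(s) scan_best_site(s, model)$logodds,
                 numeric(1))
    data.frame(round = p$round, mean_logodds = mean(lo))
  })
  do.call(rbind, rows)
}
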