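# Ground-truth simulators for every input the pipeline consumes. Defaults
# reproduce the empirical regime of the study system: per-window background
# rates lambda_R = 0.15273 (WT) and lambda_N = 0.21607 (KO), a small signal
# fraction, and 10-12 bp planted motifs.

#' Simulate paired per-window counts under the null/signal mixture
#'
#' With probability `1 - pi1` a window is null: `R ~ Pois(lambda_r)`,
#' `N ~ Pois(lambda_n)`. With probability `pi1` it is a signal window:
#' `R ~ Pois(lambda_r + enrichment)`, `N ~ Pois(lambda_n)`. Windows are
#' independent; the true labels are returned.
#'
#' @param n_windows number of windows (>= 1).
#' @param lambda_r,lambda_n background per-window rates (defaults: the
#'   empirical WT/KO estimates 0.15273 and 0.21607).
#' @param pi1 signal-window fraction in `[0, 1]`.
#' @param enrichment extra expected WT reads in a signal window.
#' @param seed optional integer seed.
#' @return data.frame with columns `R`, `N`, `D`, `signal` (logical truth).
#' @export
gen_window_counts <- function(n_windows, lambda_r = 0.15273,
                              lambda_n = 0.21607, pi1 = 0,
                              enrichment = 5, seed = NULL) {
  stopifnot(n_windows >= 1)
  if (lambda_r < 0 || lambda_n < 0 || enrichment < 0)
    stop("rates must be non-negative")
  if (pi1 < 0 || pi1 > 1) stop("pi1 must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  signal <- stats::runif(n_windows) < pi1
  R <- stats::rpois(n_windows, lambda_r + enrichment * signal)
  N <- stats::rpois(n_windows, lambda_n)
  data.frame(R = R, N = N, D = R - N, signal = signal)
}

# best-site log2-odds (PWM vs uniform background) of every sequence in an
# equal-length pool, both strands, fully vectorized
.pool_best_logodds <- function(seqs, pwm) {
  W <- nrow(pwm)
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L), L >= W)
  lpfm <- log2(pwm / rowSums(pwm))
  enc <- matrix(match(unlist(strsplit(seqs, ""), use.names = FALSE),
                      c("A", "C", "G", "T")),
                nrow = length(seqs), byrow = TRUE)
  enc_rc <- 5L - enc[, L:1, drop = FALSE]
  noff <- L - W + 1L
  best <- rep(-Inf, length(seqs))
  for (o in seq_len(noff)) {
    sf <- numeric(length(seqs)); sr <- numeric(length(seqs))
    for (t in seq_len(W)) {
      sf <- sf + lpfm[t, ][enc[, o + t - 1L]]
      sr <- sr + lpfm[t, ][enc_rc[, o + t - 1L]]
    }
    best <- pmax(best, sf, sr)
  }
  best + 2 * W   # uniform background: log2 P = -2 per base
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.sample_pwm_site <- function(pwm) {
  paste(apply(pwm, 1, function(p) sample(c("A", "C", "G", "T"), 1, prob = p)),
        collapse = "")
}

#' Position weight matrix for an exact or degenerate consensus
#'
#' Builds a W x 4 frequency matrix from an IUPAC string: allowed bases at a
#' position share `1 - slack` of the mass equally, the remaining bases share
#' `slack`.
#'
#' @param consensus IUPAC string (supports A,C,G,T,R,Y,S,W,K,M,N).
#' @param slack total probability given to disallowed bases (default 0.02).
#' @return W x 4 matrix with columns A, C, G, T.
#' @export
consensus_pwm <- function(consensus, slack = 0.02) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                N = c("A", "C", "G", "T"))
  rows <- lapply(strsplit(toupper(consensus), "")[[1]], function(ch) {
    allowed <- iupac[[ch]]
    if (is.null(allowed)) stop("unsupported IUPAC code: ", ch)
    p <- stats::setNames(rep(slack / (4 - length(allowed) + 1e-12), 4),
                         c("A", "C", "G", "T"))
    if (length(allowed) == 4) p[] <- 0.25
    else p[allowed] <- (1 - slack) / length(allowed)
    p / sum(p)
  })
  do.call(rbind, rows)
}

#' Simulate sequences with planted motif instances (ZOOPS occupancy)
#'
#' Generates independent uniform-random background sequences; each carries
#' one motif instance drawn from `pwm` at a uniform-random offset with
#' probability `occupancy`, on a uniform-random strand when
#' `both_strands = TRUE`.
#'
#' @param n number of sequences.
#' @param len sequence length in bp.
#' @param pwm planted W x 4 position weight matrix (or an IUPAC string,
#'   converted via [consensus_pwm()]).
#' @param occupancy probability a sequence carries an instance (default 0.9).
#' @param both_strands plant on either strand (default FALSE).
#' @param seed optional integer seed.
#' @return list with `seqs` (character) and `truth` (data.frame `seq`,
#'   `offset` 0-based or NA, `strand`, `site`).
#' @export
gen_motif_sequences <- function(n, len, pwm, occupancy = 0.9,
                                both_strands = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(pwm)) pwm <- consensus_pwm(pwm)
  W <- nrow(pwm)
  stopifnot(len >= W)
  seqs <- character(n)
  truth <- data.frame(seq = seq_len(n), offset = NA_integer_,
                      strand = NA_character_, site = NA_character_)
  for (i in seq_len(n)) {
    s <- .random_dna(len)
    if (stats::runif(1) < occupancy) {
      site <- .sample_pwm_site(pwm)
      strand <- if (both_strands && stats::runif(1) < 0.5) "-" else "+"
      planted <- if (strand == "-") revcomp(site) else site
      off <- sample.int(len - W + 1L, 1L) - 1L
      substr(s, off + 1L, off + W) <- planted
      truth$offset[i] <- off
      truth$strand[i] <- strand
      truth$site[i] <- site
    }
    seqs[i] <- s
  }
  list(seqs = seqs, truth = truth)
}

#' Simulate a genome with planted peaks and matched WT/KO tag tracks
#'
#' Background tags are placed uniformly at a per-base rate of
#' `lambda / width` in each sample, so the expected count of a `width`-bp
#' window equals `lambda`. Each planted peak receives `enrichment` extra WT
#' tags uniformly within its footprint, and a motif instance drawn from
#' `pwm` is embedded in the genome sequence at the peak center. Files are
#' written as FASTA + BED into `dir`; truth is returned (and serialized as
#' TSV).
#'
#' @param genome_length chromosome length in bp (single chromosome "chr1").
#' @param peaks data.frame with `start`, `end` (0-based half-open,
#'   non-overlapping) of planted peaks; may be empty.
#' @param pwm planted motif PWM or IUPAC string (or `NULL` for no motif).
#' @param lambda_r,lambda_n background per-window rates.
#' @param width window width the rates refer to (default 240).
#' @param enrichment extra WT tags per planted peak (default 10).
#' @param tss optional data.frame `pos`, `strand`, `gene` of TSS records.
#' @param dir output directory (created if needed).
#' @param seed optional integer seed.
#' @return list of paths (`genome`, `wt`, `ko`, `chrom_sizes`, `tss`,
#'   `truth`) plus the `truth` data.frame (planted peaks and motif sites).
#' @export
gen_genome_and_tags <- function(genome_length, peaks = NULL, pwm = NULL,
                                lambda_r = 0.15273, lambda_n = 0.21607,
                                width = 240L, enrichment = 10L,
                                tss = NULL, dir = tempfile("simgenome"),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(peaks))
    peaks <- data.frame(start = integer(0), end = integer(0))
  if (nrow(peaks) > 1L) {
    o <- order(peaks$start)
    peaks <- peaks[o, , drop = FALSE]
    if (any(peaks$start[-1] < peaks$end[-nrow(peaks)]))
      stop("planted peaks must not overlap")
  }
  if (nrow(peaks) && any(peaks$start < 0 | peaks$end > genome_length))
    stop("planted peaks must lie within the genome")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  genome <- .random_dna(genome_length)
  if (is.character(pwm)) pwm <- consensus_pwm(pwm)

  truth <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), motif_offset = integer(0),
                      motif_site = character(0))
  wt_pos <- integer(0); ko_pos <- integer(0)
  if (nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      st <- peaks$start[i]; en <- peaks$end[i]
      site <- NA_character_; moff <- NA_integer_
      if (!is.null(pwm) && (en - st) >= nrow(pwm)) {
        site <- .sample_pwm_site(pwm)
        moff <- st + ((en - st) - nrow(pwm)) %/% 2L
        substr(genome, moff + 1L, moff + nrow(pwm)) <- site
      }
      truth <- rbind(truth, data.frame(chrom = "chr1", start = st, end = en,
                                       motif_offset = moff,
                                       motif_site = site))
      wt_pos <- c(wt_pos, st + sample.int(en - st, enrichment,
                                          replace = TRUE) - 1L)
    }
  }
  n_bg_wt <- stats::rpois(1, genome_length * lambda_r / width)
  n_bg_ko <- stats::rpois(1, genome_length * lambda_n / width)
  wt_pos <- c(wt_pos, sample.int(genome_length, n_bg_wt, replace = TRUE) - 1L)
  ko_pos <- c(ko_pos, sample.int(genome_length, n_bg_ko, replace = TRUE) - 1L)

  paths <- list(genome = file.path(dir, "genome.fa"),
                wt = file.path(dir, "tags_wt.bed"),
                ko = file.path(dir, "tags_ko.bed"),
                chrom_sizes = file.path(dir, "chrom.sizes"),
                tss = NULL,
                truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chr1 = genome)), paths$genome)
  .write_tag_bed <- function(pos, path) {
    if (length(pos) == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    pos <- sort(pos)
    df <- data.frame("chr1", pos, pmin(pos + 35L, genome_length),
                     ".", 0L, "+")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  .write_tag_bed(wt_pos, paths$wt)
  .write_tag_bed(ko_pos, paths$ko)
  writeLines(sprintf("chr1\t%d", genome_length), paths$chrom_sizes)
  if (!is.null(tss)) {
    paths$tss <- file.path(dir, "tss.bed")
    utils::write.table(
      data.frame("chr1", tss$pos, tss$pos + 1L, tss$gene, 0L, tss$strand),
      paths$tss, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(truth_table = truth))
}

#' Simulate rounds of binding-site selection (SELEX)
#'
#' Round 0 is a pool of uniform-random inserts. Each later round keeps a
#' sequence with probability `plogis(selection_strength * best-site
#' log-odds)` of the planted PWM over the insert+flank context, then
#' replenishes the pool to `pool_size` by resampling survivors with
#' replacement (the PCR-amplification surrogate).
#'
#' @param pool_size sequences per round (>= 10).
#' @param insert_len random insert length (default 16).
#' @param flank_5p,flank_3p fixed flanks added for scoring and output.
#' @param pwm planted PWM or IUPAC string defining the selected motif.
#' @param rounds number of selection rounds after round 0 (default 4).
#' @param selection_strength logistic slope on the log-odds scale; 0 means
#'   no selection.
#' @param seed optional integer seed.
#' @return list of `selex_pool` objects (rounds 0..`rounds`).
#' @export
gen_selex <- function(pool_size, insert_len = 16L, flank_5p = "",
                      flank_3p = "", pwm, rounds = 4L,
                      selection_strength = 1, seed = NULL) {
  stopifnot(pool_size >= 10L)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(pwm)) pwm <- consensus_pwm(pwm)
  inserts <- vapply(seq_len(pool_size), function(i) .random_dna(insert_len),
                    character(1))
  pools <- list(selex_pool(inserts, 0L, flank_5p, flank_3p))
  for (r in seq_len(rounds)) {
    prev <- pools[[r]]$sequences
    ctx <- paste0(flank_5p, prev, flank_3p)
    lo <- .pool_best_logodds(ctx, pwm)
    keep <- stats::runif(pool_size) < stats::plogis(selection_strength * lo)
    survivors <- prev[keep]
    if (length(survivors) == 0L) survivors <- prev  # selection failed; carry over
    nxt <- sample(survivors, pool_size, replace = TRUE)
    pools[[r + 1L]] <- selex_pool(nxt, r, flank_5p, flank_3p)
  }
  pools
}

#' Simulate a two-group expression table
#'
#' Normal draws per genotype group with the given means and SDs; the
#' reference (normalization) measurement is fixed at 1 so the target column
#' is already the normalized abundance.
#'
#' @param mean_wt,mean_ko group means.
#' @param sd_wt,sd_ko group standard deviations (>= 0).
#' @param n per-group sample size.
#' @param seed optional integer seed.
#' @return data.frame in the [read_expression_table()] layout.
#' @export
gen_expression <- function(mean_wt = 1, mean_ko = 1, sd_wt = 0.1,
                           sd_ko = 0.1, n = 8L, seed = NULL) {
  stopifnot(sd_wt >= 0, sd_ko >= 0, n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    animal = sprintf("%s%02d", rep(c("wt", "ko"), each = n), c(1:n, 1:n)),
    genotype = rep(c("WT", "KO"), each = n),
    target = c(stats::rnorm(n, mean_wt, sd_wt),
               stats::rnorm(n, mean_ko, sd_ko)),
    reference = 1)
}
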