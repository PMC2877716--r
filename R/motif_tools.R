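.BASES <- c("A", "C", "G", "T")

.encode_seq <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], .BASES)  # N -> NA
  as.integer(v)
}

.decode_seq <- function(enc) paste(.BASES[enc], collapse = "")

.revcomp_enc <- function(enc) rev(5L - enc)

#' Reverse complement of a nucleotide string
#' @param seq character scalar over ACGTN.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Train an order-k Markov background model
#'
#' Conditional next-base probabilities for every context length 0..k with
#' add-one pseudocounts. Shorter contexts at sequence starts fall back to the
#' corresponding lower-order distribution; positions involving `N` are
#' skipped during training.
#'
#' @param seqs character vector of nucleotide sequences.
#' @param k Markov order (default 3).
#' @return a `markov_bg` object.
#' @export
train_background <- function(seqs, k = 3L) {
  k <- as.integer(k)
  if (k < 0L) stop("background order must be >= 0")
  counts <- lapply(0:k, function(m) matrix(0, nrow = 4^m, ncol = 4))
  for (s in seqs) {
    enc <- .encode_seq(s)
    L <- length(enc)
    for (m in 0:k) {
      if (L < m + 1L) next
      pos <- (m + 1L):L
      ctx <- rep(0L, length(pos))
      ok <- !is.na(enc[pos])
      for (j in seq_len(m)) {
        prev <- enc[pos - j]
        ok <- ok & !is.na(prev)
        ctx <- ctx + (ifelse(is.na(prev), 0L, prev - 1L)) * 4L^(j - 1L)
      }
      if (!any(ok)) next
      idx <- cbind(ctx[ok] + 1L, enc[pos][ok])
      tab <- table(factor(idx[, 1], levels = seq_len(4^m)),
                   factor(idx[, 2], levels = 1:4))
      counts[[m + 1L]] <- counts[[m + 1L]] + unclass(tab)
    }
  }
  logp <- lapply(counts, function(cm) {
    pr <- (cm + 1) / (rowSums(cm) + 4)
    log2(pr)
  })
  structure(list(k = k, logp = logp), class = "markov_bg")
}

# log2 probability of base at each position given its (within-sequence,
# order-capped) context; list of k+1 vectors, L_m defined for pos > m.
.bg_position_logp <- function(bg, enc) {
  L <- length(enc)
  lapply(0:bg$k, function(m) {
    out <- rep(NA_real_, L)
    if (L < m + 1L) return(out)
    pos <- (m + 1L):L
    ctx <- rep(0L, length(pos))
    ok <- !is.na(enc[pos])
    for (j in seq_len(m)) {
      prev <- enc[pos - j]
      ok <- ok & !is.na(prev)
      ctx <- ctx + (ifelse(is.na(prev), 0L, prev - 1L)) * 4L^(j - 1L)
    }
    v <- rep(-1000, length(pos))
    v[ok] <- bg$logp[[m + 1L]][cbind(ctx[ok] + 1L, enc[pos][ok])]
    out[pos] <- v
    out
  })
}

# log2 background probability of every W-window of enc (contexts truncated
# at the window start, so the value depends only on the window's bases)
.bg_window_logp <- function(bg, enc, W) {
  L <- length(enc)
  if (L < W) return(numeric(0))
  Lm <- .bg_position_logp(bg, enc)
  noff <- L - W + 1L
  s <- numeric(noff)
  for (t in seq_len(W)) {
    m <- min(bg$k, t - 1L)
    s <- s + Lm[[m + 1L]][(t):(t + noff - 1L)]
  }
  s
}

#' Total log2 probability of a sequence under a background model
#'
#' @param bg a [train_background()] model.
#' @param seq nucleotide string.
#' @return log2 probability (N positions contribute 0).
#' @export
background_logp <- function(bg, seq) {
  enc <- .encode_seq(seq)
  Lm <- .bg_position_logp(bg, enc)
  tot <- 0
  for (pos in seq_along(enc)) {
    if (is.na(enc[pos])) next
    m <- min(bg$k, pos - 1L)
    tot <- tot + Lm[[m + 1L]][pos]
  }
  tot
}

.pfm_from_sites <- function(site_mat, W, pseudocount = 0.25) {
  pfm <- matrix(pseudocount, nrow = W, ncol = 4,
                dimnames = list(NULL, .BASES))
  if (!is.null(site_mat) && nrow(site_mat) > 0) {
    for (j in seq_len(W)) {
      tb <- tabulate(site_mat[, j], nbins = 4L)
      pfm[j, ] <- pfm[j, ] + tb
    }
  }
  pfm / rowSums(pfm)
}

#' Per-column information content of a position frequency matrix
#'
#' `IC_j = 2 + sum_b p_jb log2 p_jb` bits (the sequence-logo convention for a
#' uniform genomic base composition), with `0 * log 0 := 0`.
#'
#' @param pfm W x 4 matrix of column frequencies (rows sum to 1).
#' @return numeric vector of per-position bits in `[0, 2]`.
#' @export
information_content <- function(pfm) {
  apply(pfm, 1, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

.IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' IUPAC degenerate consensus of a position frequency matrix
#'
#' Per column: the single base if its frequency is at least `single`; the
#' two-base IUPAC code if the top two bases jointly reach `double` (and no
#' single base dominates); otherwise `N`.
#'
#' @param pfm W x 4 frequency matrix (columns A, C, G, T).
#' @param single single-base threshold (default 0.6).
#' @param double two-base threshold (default 0.8).
#' @return consensus string of length `nrow(pfm)`.
#' @export
iupac_consensus <- function(pfm, single = 0.6, double = 0.8) {
  paste(apply(pfm, 1, function(p) {
    o <- order(p, decreasing = TRUE)
    if (p[o[1]] >= single) return(.BASES[o[1]])
    if (p[o[1]] + p[o[2]] >= double) {
      pair <- paste(sort(.BASES[o[1:2]]), collapse = "")
      return(.IUPAC2[[pair]])
    }
    "N"
  }), collapse = "")
}

.build_motif_model <- function(enc_f, assign_off, assign_str, W, bg,
                               pseudocount, seq_names = NULL) {
  present <- which(assign_off >= 0L)
  site_mat <- NULL
  sites <- data.frame(seq = integer(0), offset = integer(0),
                      strand = character(0), site = character(0))
  if (length(present)) {
    site_mat <- t(vapply(present, function(i) {
      o <- assign_off[i]
      if (assign_str[i] == 0L) enc_f[[i]][(o + 1L):(o + W)]
      else .revcomp_enc(enc_f[[i]])[(length(enc_f[[i]]) - W - o + 1L):
                                      (length(enc_f[[i]]) - o)]
    }, integer(W)))
    sites <- data.frame(
      seq = present,
      offset = assign_off[present],
      strand = ifelse(assign_str[present] == 0L, "+", "-"),
      site = apply(site_mat, 1, .decode_seq))
  }
  pfm <- .pfm_from_sites(site_mat, W, pseudocount)
  score <- 0
  if (length(present)) {
    lpfm <- log2(pfm)
    for (r in seq_len(nrow(site_mat))) {
      site_lp <- sum(lpfm[cbind(seq_len(W), site_mat[r, ])])
      bg_lp <- background_logp(bg, sites$site[r])
      score <- score + (site_lp - bg_lp)
    }
  }
  structure(list(width = W, pfm = pfm, ic = information_content(pfm),
                 consensus = iupac_consensus(pfm), score = score,
                 sites = sites, n_sites = length(present), background = bg),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif model: width %d, %d site(s), consensus %s, score %.1f\n",
              x$width, x$n_sites, x$consensus, x$score))
  invisible(x)
}

#' Gibbs-sampling motif discovery (ZOOPS, both strands)
#'
#' Searches a set of sequences for a shared fixed-width motif with a
#' collapsed Gibbs sampler under a zero-or-one-occurrence-per-sequence
#' (ZOOPS) model. Each iteration withholds one sequence, rebuilds the
#' position frequency matrix from the remaining site assignments
#' (pseudocount `pseudocount` per base), and resamples the withheld
#' sequence's site across all offsets on both strands plus an "absent"
#' state, with a uniform positional prior. Site likelihoods are weighed
#' against an order-k Markov background. The best-scoring model over
#' `trials` independent restarts is returned; results are deterministic for
#' a fixed RNG seed.
#'
#' @param seqs character vector of sequences; sequences shorter than `width`
#'   are skipped with a warning.
#' @param width motif width in bp (default 10).
#' @param trials independent sampler restarts (default 20).
#' @param iterations site-resampling steps per trial (default 10000).
#' @param background a [train_background()] model; trained on `seqs`
#'   (order 3) when `NULL`.
#' @param seed optional integer seed applied via [set.seed()].
#' @param pseudocount per-base pseudocount for the PFM (default 0.25).
#' @param absent_prior prior weight of the "no site" state (default 0.1).
#' @return a `motif_model`: `pfm` (width x 4), `ic`, `consensus`, `score`
#'   (total log2 likelihood ratio over sites), `sites`, `background`.
#' @export
gibbs_search <- function(seqs, width = 10L, trials = 20L, iterations = 10000L,
                         background = NULL, seed = NULL, pseudocount = 0.25,
                         absent_prior = 0.1) {
  W <- as.integer(width)
  if (!is.null(seed)) set.seed(seed)
  keep <- nchar(seqs) >= W
  if (!any(keep)) stop("all sequences are shorter than the motif width")
  if (any(!keep))
    warning(sum(!keep), " sequence(s) shorter than the motif width skipped")
  seqs <- seqs[keep]
  if (is.null(background)) background <- train_background(seqs, k = 3L)

  enc_f <- lapply(seqs, .encode_seq)
  if (any(vapply(enc_f, anyNA, logical(1))))
    stop("N bases are not supported inside searched sequences")
  bg_f <- lapply(enc_f, function(e) .bg_window_logp(background, e, W))
  # bg prob of the minus-strand site covering forward offsets [o, o+W):
  # window o' on the reverse complement maps to forward offset L - W - o'
  bg_r <- lapply(enc_f, function(e) {
    rev(.bg_window_logp(background, .revcomp_enc(e), W))
  })

  n <- length(enc_f)

  # seeded restart: align every sequence to its closest match (by Hamming
  # distance, either strand) of a randomly drawn seed W-mer
  .seed_init <- function() {
    i0 <- sample.int(n, 1L)
    o0 <- sample.int(length(enc_f[[i0]]) - W + 1L, 1L) - 1L
    seed_site <- enc_f[[i0]][(o0 + 1L):(o0 + W)]
    off <- integer(n); str <- integer(n)
    for (i in seq_len(n)) {
      e <- enc_f[[i]]
      er <- .revcomp_enc(e)
      noff <- length(e) - W + 1L
      mf <- integer(noff); mr <- integer(noff)
      for (t in seq_len(W)) {
        mf <- mf + (e[t:(t + noff - 1L)] == seed_site[t])
        mr <- mr + (er[t:(t + noff - 1L)] == seed_site[t])
      }
      mr <- rev(mr)  # index by forward offset
      if (max(mf) >= max(mr)) {
        off[i] <- which.max(mf) - 1L; str[i] <- 0L
      } else {
        off[i] <- which.max(mr) - 1L; str[i] <- 1L
      }
    }
    list(off = off, str = str)
  }

  best <- NULL
  for (tr in seq_len(trials)) {
    if (tr %% 2L == 0L) {
      ini <- .seed_init()
      init_off <- ini$off
      init_str <- ini$str
    } else {
      init_off <- vapply(enc_f, function(e) {
        sample.int(length(e) - W + 1L, 1L) - 1L
      }, integer(1))
      init_str <- sample(c(0L, 1L), n, replace = TRUE)
    }
    res <- gibbs_run(enc_f, bg_f, bg_r, W, as.integer(iterations),
                     pseudocount, absent_prior, init_off, init_str)
    model <- .build_motif_model(enc_f, res$offset, res$strand, W, background,
                                pseudocount)
    if (is.null(best) || model$score > best$score) best <- model
  }
  best
}

#' Total log-likelihood-ratio score of a motif model
#'
#' `sum over sites of [log2 P(site | PFM) - log2 P(site | background)]`;
#' additive over sites and zero for an empty site list.
#'
#' @param model a `motif_model`.
#' @param background a [train_background()] model (default: the model's own).
#' @return numeric score.
#' @export
score_motif <- function(model, background = model$background) {
  if (nrow(model$sites) == 0L) return(0)
  lpfm <- log2(model$pfm)
  sum(vapply(model$sites$site, function(s) {
    enc <- .encode_seq(s)
    sum(lpfm[cbind(seq_along(enc), enc)]) - background_logp(background, s)
  }, numeric(1)))
}

#' Best motif site in a sequence
#'
#' Exhaustive scan of all offsets on both strands for the maximal log-odds
#' (PFM vs background) site. Ties break toward the smallest offset, then the
#' plus strand.
#'
#' @param seq nucleotide string.
#' @param model a `motif_model`.
#' @param background background model (default: the model's own).
#' @param floor log-odds floor; a best site below it is reported with status
#'   `"none"` (default `-Inf`: always report).
#' @return list with `status` (`"ok"`, `"none"`, or `"too short"`), and for
#'   scanned sequences `offset` (0-based), `strand`, `site`, `logodds`.
#' @export
scan_best_site <- function(seq, model, background = model$background,
                           floor = -Inf) {
  W <- model$width
  enc <- .encode_seq(seq)
  if (length(enc) < W)
    return(list(status = "too short", offset = NA_integer_,
                strand = NA_character_, site = NA_character_,
                logodds = NA_real_))
  lpfm <- log2(model$pfm)
  noff <- length(enc) - W + 1L
  lik_f <- numeric(noff); lik_r <- numeric(noff)
  enc_r <- .revcomp_enc(enc)
  for (t in seq_len(W)) {
    lik_f <- lik_f + lpfm[t, ][enc[t:(t + noff - 1L)]]
    lik_r <- lik_r + lpfm[t, ][enc_r[t:(t + noff - 1L)]]
  }
  lo_f <- lik_f - .bg_window_logp(background, enc, W)
  bgw_r <- rev(.bg_window_logp(background, enc_r, W))
  lo_r <- rev(lik_r) - bgw_r   # indexed by forward offset
  # tie-break: smallest offset, then + strand
  cand <- rbind(data.frame(offset = 0:(noff - 1L), strand = "+",
                           logodds = lo_f),
                data.frame(offset = 0:(noff - 1L), strand = "-",
                           logodds = lo_r))
  cand <- cand[order(-cand$logodds, cand$offset, cand$strand), ]
  top <- cand[1L, ]
  site <- if (top$strand == "+") {
    .decode_seq(enc[(top$offset + 1L):(top$offset + W)])
  } else {
    .decode_seq(.revcomp_enc(enc[(top$offset + 1L):(top$offset + W)]))
  }
  if (top$logodds < floor)
    return(list(status = "none", offset = NA_integer_,
                strand = NA_character_, site = NA_character_,
                logodds = top$logodds))
  list(status = "ok", offset = top$offset, strand = top$strand,
       site = site, logodds = top$logodds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a 10-mer response-element site by positional base requirements
#'
#' Binding of the factor to its 10-bp element depends unevenly on position:
#' changes at the critical positions (3, 6, 7, 8 - the A...GAG core)
#' essentially abolish competition in vitro, changes at positions 1, 9 or 10
#' partially impair it, and positions 2, 4 and 5 are tolerant. A site is
#' `Low` affinity if any critical position deviates from the reference,
#' else `Medium` if any moderate position deviates, else `High`.
#'
#' @param site 10-mer over ACGT.
#' @param reference reference high-affinity site (default the Camk2n1-peak
#'   instance `"AAAGCGAGGC"`).
#' @param critical 1-based positions whose change abolishes binding.
#' @param moderate 1-based positions whose change partially impairs binding.
#' @return list with `site`, `category` (`High`/`Medium`/`Low`) and
#'   `changed` (integer positions deviating from the reference at
#'   constrained positions).
#' @export
classify_affinity <- function(site, reference = "AAAGCGAGGC",
                              critical = c(3L, 6L, 7L, 8L),
                              moderate = c(1L, 9L, 10L)) {
  site <- toupper(site)
  if (nchar(site) != nchar(reference))
    stop("site must have length ", nchar(reference))
  sv <- strsplit(site, "")[[1]]
  if (!all(sv %in% .BASES)) stop("site must contain only A, C, G, T")
  rv <- strsplit(toupper(reference), "")[[1]]
  constrained <- sort(c(critical, moderate))
  changed <- constrained[sv[constrained] != rv[constrained]]
  category <- if (any(changed %in% critical)) "Low"
  else if (any(changed %in% moderate)) "Medium"
  else "High"
  list(site = site, category = category, changed = changed)
}
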