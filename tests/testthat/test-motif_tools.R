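test_that("background training applies add-one pseudocounts with fallback", {
  bg <- train_background("AAAAAAAA", k = 3)
  # context AAA seen 5x, always followed by A: (5+1)/(5+4)
  ctx_aaa <- 1L  # context code 0 + 1
  pA <- 2^bg$logp[[4]][ctx_aaa, 1]
  expect_equal(pA, (5 + 1) / (5 + 4))
  expect_true(all(pA > 2^bg$logp[[4]][ctx_aaa, 2:4]))
  # order 0 on ACGT: uniform (1+1)/(4+4)
  bg0 <- train_background("ACGT", k = 0)
  expect_equal(as.numeric(2^bg0$logp[[1]]), rep(0.25, 4))
  # every conditional distribution sums to 1
  bg3 <- train_background(c("ACGTACGGTTAACCGG", "TTTTGGGCCAA"), k = 3)
  for (m in seq_along(bg3$logp))
    expect_equal(unname(rowSums(2^bg3$logp[[m]])), rep(1, 4^(m - 1)),
                 tolerance = 1e-9)
  expect_error(train_background("ACGT", k = -1), ">= 0")
})

test_that("sequences are likelier under their own background than a foreign one", {
  set.seed(23)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    own <- train_background(s, k = 2)
    foreign <- train_background(chartr("ACGT", "CAGT", s), k = 2)
    expect_gt(background_logp(own, s), background_logp(foreign, s))
  }
})

test_that("information content follows the 2 + sum p log2 p convention", {
  expect_equal(information_content(matrix(c(1, 0, 0, 0), 1)), 2)
  expect_equal(information_content(matrix(rep(0.25, 4), 1)), 0)
  expect_equal(information_content(matrix(c(0.5, 0.5, 0, 0), 1)), 1)
  pfm <- rbind(c(1, 0, 0, 0), rep(0.25, 4), c(0.5, 0, 0.5, 0))
  expect_equal(information_content(pfm), c(2, 0, 1))
  expect_true(all(information_content(pfm) >= 0 &
                    information_content(pfm) <= 2))
})

test_that("IUPAC consensus thresholds: single base, two-base code, N", {
  expect_equal(iupac_consensus(matrix(c(1, 0, 0, 0), 1)), "A")
  expect_equal(iupac_consensus(matrix(c(0.5, 0, 0.5, 0), 1)), "R")
  expect_equal(iupac_consensus(matrix(c(0.3, 0.3, 0.2, 0.2), 1)), "N")
  expect_equal(iupac_consensus(matrix(c(0.6, 0.2, 0.1, 0.1), 1)), "A")
  expect_equal(iupac_consensus(matrix(c(0.1, 0.45, 0.05, 0.4), 1)), "Y")
  # row-order permutation of the matrix permutes the string
  pfm <- rbind(c(0.9, 0.05, 0.03, 0.02), c(0.1, 0.1, 0.1, 0.7),
               c(0.45, 0.45, 0.05, 0.05))
  cons <- iupac_consensus(pfm)
  expect_equal(cons, "ATM")
  perm <- c(3, 1, 2)
  expect_equal(iupac_consensus(pfm[perm, ]),
               paste(strsplit(cons, "")[[1]][perm], collapse = ""))
})

test_that("affinity classification follows the positional rules", {
  ref <- "AAAGCGAGGC"
  expect_equal(classify_affinity(ref)$category, "High")
  expect_equal(classify_affinity("GAAGCGAGGC")$category, "Medium")  # pos 1
  expect_equal(classify_affinity("AAAGCGCGGC")$category, "Low")     # pos 7
  expect_equal(classify_affinity(mutate_at(ref, 4))$category, "High")
  # Low takes precedence over Medium when both kinds of changes occur
  both <- mutate_at(mutate_at(ref, 1), 3)
  expect_equal(classify_affinity(both)$category, "Low")
  expect_error(classify_affinity("AAAG"), "length")
  expect_error(classify_affinity("AAAGCGAGGN"), "A, C, G, T")
})

test_that("affinity categories partition all 10-mers (enumeration oracle)", {
  ref <- strsplit("AAAGCGAGGC", "")[[1]]
  critical <- c(3, 6, 7, 8); moderate <- c(1, 9, 10)
  # enumerate all 4^10 sites as a base-4 digit matrix and classify vectorized
  n <- 4^10
  digits <- matrix(0L, n, 10)
  idx <- 0:(n - 1)
  for (j in 1:10) {
    digits[, j] <- idx %% 4L
    idx <- idx %/% 4L
  }
  refd <- match(ref, c("A", "C", "G", "T")) - 1L
  crit_change <- rowSums(digits[, critical, drop = FALSE] !=
                           rep(refd[critical], each = n)) > 0
  mod_change <- rowSums(digits[, moderate, drop = FALSE] !=
                          rep(refd[moderate], each = n)) > 0
  n_low <- sum(crit_change)
  n_med <- sum(!crit_change & mod_change)
  n_high <- sum(!crit_change & !mod_change)
  expect_equal(n_high, 4^3)             # only positions 2, 4, 5 free
  expect_equal(n_med, 4^3 * (4^3 - 1))  # some change among 1, 9, 10
  expect_equal(n_high + n_med + n_low, n)
  # spot-check the scalar classifier against the enumeration on a sample
  set.seed(29)
  for (i in sample.int(n, 50)) {
    site <- paste(c("A", "C", "G", "T")[digits[i, ] + 1L], collapse = "")
    expected <- if (crit_change[i]) "Low" else if (mod_change[i]) "Medium"
    else "High"
    expect_equal(classify_affinity(site)$category, expected)
  }
})

test_that("best-site scanning: orientation, ties, planted offset, sentinels", {
  set.seed(31)
  cons <- "AAAGCGAGGC"
  sim <- gen_motif_sequences(40, 80, cons, occupancy = 1, seed = 31)
  model <- gibbs_search(sim$seqs, width = 10, trials = 5, iterations = 2000,
                        seed = 1)
  hit <- scan_best_site(cons, model)
  expect_equal(hit$status, "ok")
  expect_equal(hit$offset, 0L)
  rc <- scan_best_site(revcomp(cons), model)
  expect_equal(rc$offset, 0L)
  expect_equal(rc$logodds, hit$logodds, tolerance = 1e-9)
  expect_setequal(c(hit$strand, rc$strand), c("+", "-"))
  # planted site at a known offset is found by the exhaustive scan
  s <- rand_dna(80)
  substr(s, 38, 47) <- cons
  found <- scan_best_site(s, model)
  expect_equal(found$offset, 37L)
  expect_true(found$site %in% c(cons, revcomp(cons)))
  expect_equal(scan_best_site("ACGT", model)$status, "too short")
  expect_equal(scan_best_site(s, model, floor = 1e6)$status, "none")
})

test_that("motif score is additive over sites and zero when empty", {
  set.seed(37)
  sim <- gen_motif_sequences(30, 60, "AAAGCGAGGC", occupancy = 1, seed = 37)
  m <- gibbs_search(sim$seqs, width = 10, trials = 5, iterations = 2000,
                    seed = 2)
  expect_equal(score_motif(m), m$score, tolerance = 1e-6)
  empty <- m
  empty$sites <- m$sites[0, ]
  expect_equal(score_motif(empty), 0)
  # near-deterministic PFM scores one consensus site at ~ W * log2((1-3e)/q)
  eps <- 1e-3
  pfm <- matrix(eps, 10, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pfm[cbind(1:10, match(strsplit("AAAGCGAGGC", "")[[1]],
                        c("A", "C", "G", "T")))] <- 1 - 3 * eps
  bg0 <- train_background(character(0), k = 0)  # uniform background
  fake <- structure(list(width = 10L, pfm = pfm, background = bg0,
                         sites = data.frame(seq = 1L, offset = 0L,
                                            strand = "+",
                                            site = "AAAGCGAGGC")),
                    class = "motif_model")
  expect_equal(score_motif(fake), 10 * log2((1 - 3 * eps) / 0.25),
               tolerance = 1e-9)
})

test_that("Gibbs sampler recovers planted motifs on both strands", {
  plant <- "AAAGCGAGGC"; rc <- revcomp(plant)
  recovered <- 0L
  for (s in 1:5) {
    sim <- gen_motif_sequences(50, 100, plant, occupancy = 0.9,
                               both_strands = TRUE, seed = 500 + s)
    m <- gibbs_search(sim$seqs, width = 10, trials = 10, iterations = 10000,
                      seed = s)
    d <- min(hamming(m$consensus, plant), hamming(m$consensus, rc))
    if (d <= 1) recovered <- recovered + 1L
  }
  expect_gte(recovered, 4L)
  # strand-invariance: plants reverse-complemented in half the sequences
  sim2 <- gen_motif_sequences(50, 100, plant, occupancy = 1,
                              both_strands = TRUE, seed = 601)
  expect_true(any(sim2$truth$strand == "-") && any(sim2$truth$strand == "+"))
  m2 <- gibbs_search(sim2$seqs, width = 10, trials = 10, iterations = 10000,
                     seed = 6)
  expect_lte(min(hamming(m2$consensus, plant), hamming(m2$consensus, rc)), 1)
})

test_that("sampler is deterministic under a fixed seed and warns on short input", {
  sim <- gen_motif_sequences(20, 60, "AAAGCGAGGC", occupancy = 1, seed = 41)
  m1 <- gibbs_search(sim$seqs, width = 10, trials = 3, iterations = 500,
                     seed = 9)
  m2 <- gibbs_search(sim$seqs, width = 10, trials = 3, iterations = 500,
                     seed = 9)
  expect_identical(m1$pfm, m2$pfm)
  expect_identical(m1$sites, m2$sites)
  expect_warning(
    gibbs_search(c(sim$seqs, "ACGT"), width = 10, trials = 1,
                 iterations = 100, seed = 1),
    "skipped")
  expect_error(gibbs_search(c("ACGT", "GGG"), width = 10), "shorter")
})
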