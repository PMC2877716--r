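#' Pipeline configuration with study defaults
#'
#' Collects every tunable of the end-to-end analysis. Defaults are the
#' study conditions: 240 bp windows every 10 bp, locFDR threshold
#' `f_p = 0.01`, 100 bp peak merging, discarding regions of at most 20 bp,
#' a 10 bp motif searched with 20 trials of 10,000 Gibbs iterations against
#' an order-3 background.
#'
#' @param window_width,window_step sliding-window geometry (bp).
#' @param f_p locFDR threshold.
#' @param p0 null weight, or `"auto"` for central matching.
#' @param lambda_estimator `"mean"` or `"null_fit"` (see
#'   [estimate_lambda()]).
#' @param merge_gap maximum inter-peak gap merged (bp).
#' @param min_len peaks of at most this length are set aside (bp).
#' @param motif_width,motif_trials,motif_iterations,bg_order Gibbs sampler
#'   settings.
#' @param d0 optional explicit critical difference overriding the fit.
#' @param motif_floor log-odds floor below which a best site is reported as
#'   `"none"`.
#' @param affinity_reference reference 10-mer for the affinity classifier;
#'   scanned sites are classified in whichever orientation better matches
#'   it.
#' @param seed integer seed for the sampler.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(window_width = 240L, window_step = 10L,
                            f_p = 0.01, p0 = "auto",
                            lambda_estimator = "mean", merge_gap = 100L,
                            min_len = 20L, motif_width = 10L,
                            motif_trials = 20L, motif_iterations = 10000L,
                            bg_order = 3L, d0 = NULL, motif_floor = 0,
                            affinity_reference = "AAAGCGAGGC", seed = 1L) {
  structure(list(window_width = as.integer(window_width),
                 window_step = as.integer(window_step), f_p = f_p, p0 = p0,
                 lambda_estimator = lambda_estimator,
                 merge_gap = as.integer(merge_gap),
                 min_len = as.integer(min_len),
                 motif_width = as.integer(motif_width),
                 motif_trials = as.integer(motif_trials),
                 motif_iterations = as.integer(motif_iterations),
                 bg_order = as.integer(bg_order), d0 = d0,
                 motif_floor = motif_floor,
                 affinity_reference = affinity_reference,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the knockout-controlled ChIP-seq analysis end to end
#'
#' Stages, in order: window counting (WT vs KO), per-window rate estimation,
#' Skellam-null locFDR fit, significance calling at the critical difference,
#' peak assembly, close-peak merging, short-peak removal, Gibbs motif
#' discovery over the kept peak sequences, best-site scanning and affinity
#' classification per peak, and nearest-TSS annotation. Returns the peak
#' table (with `"none"` / `"too short"` motif flags preserved) plus a run
#' log recording every parameter, the fitted rates, `p0` and `d0`.
#'
#' @param wt_path,ko_path tag BED files for the WT and KO pulldowns.
#' @param chrom_sizes_path two-column chromosome size table.
#' @param mask_path optional repeat-mask BED.
#' @param tss_path optional TSS BED.
#' @param genome_path optional genome FASTA; motif stages run only when
#'   present.
#' @param config a [pipeline_config()].
#' @return list with `peak_table`, `peaks`, `too_short`, `windows_model`
#'   (the `locfdr_model`), `motif` (a `motif_model` or `NULL`),
#'   `tss_distances`, and `log`.
#' @export
run_pipeline <- function(wt_path, ko_path, chrom_sizes_path,
                         mask_path = NULL, tss_path = NULL,
                         genome_path = NULL, config = pipeline_config()) {
  ann <- read_annotation(chrom_sizes_path, tss_path, mask_path)
  wt <- read_tags(wt_path, "WT", ann)
  ko <- read_tags(ko_path, "KO", ann)
  spec <- window_spec(config$window_width, config$window_step)

  windows <- count_windows(wt, ko, ann, spec)
  usable <- windows[!windows$excluded, , drop = FALSE]
  lam_r <- estimate_lambda(usable$R, config$lambda_estimator)
  lam_n <- estimate_lambda(usable$N, config$lambda_estimator)
  null <- skellam_null(lam_r, lam_n)
  model <- fit_locfdr(usable$D, null, p0 = config$p0, f_p = config$f_p)

  windows <- call_significant(windows, model, d0 = config$d0)
  peaks <- assemble_peaks(windows, spec)
  peaks <- merge_close_peaks(peaks, config$merge_gap)
  flt <- filter_short(peaks, config$min_len)
  kept <- flt$kept

  motif <- NULL
  tab_motif <- rep("", nrow(kept))
  tab_aff <- rep("", nrow(kept))
  if (!is.null(genome_path) && nrow(kept) > 0L) {
    genome <- read_genome(genome_path)
    seqs <- peak_sequences(kept, genome)
    searchable <- nchar(seqs) >= config$motif_width
    if (any(searchable)) {
      bg <- train_background(seqs[searchable], k = config$bg_order)
      motif <- gibbs_search(seqs[searchable], width = config$motif_width,
                            trials = config$motif_trials,
                            iterations = config$motif_iterations,
                            background = bg, seed = config$seed)
      ref <- config$affinity_reference
      for (i in which(searchable)) {
        hit <- scan_best_site(seqs[i], motif, floor = config$motif_floor)
        if (hit$status == "ok") {
          # classify in the orientation that better matches the reference
          cls <- tryCatch({
            fwd <- classify_affinity(hit$site, reference = ref)
            rev <- classify_affinity(revcomp(hit$site), reference = ref)
            if (length(rev$changed) < length(fwd$changed)) rev else fwd
          }, error = function(e) NULL)
          if (is.null(cls)) {
            tab_motif[i] <- hit$site
          } else {
            tab_motif[i] <- cls$site
            tab_aff[i] <- cls$category
          }
        } else tab_motif[i] <- hit$status
      }
      tab_motif[!searchable] <- "too short"
    }
  }

  tss_dist <- NULL
  tab_gene <- rep("", nrow(kept))
  if (!is.null(tss_path) && nrow(kept) > 0L && nrow(ann$tss) > 0L) {
    tss_dist <- nearest_tss(kept, ann)
    keep10 <- !is.na(tss_dist$distance) & tss_dist$within_10kb
    tab_gene[keep10] <- tss_dist$gene[keep10]
  }

  tab <- peak_table(kept$chrom, kept$start, kept$end,
                    gene = tab_gene, motif = tab_motif, affinity = tab_aff)
  if (nrow(flt$too_short)) {
    short_tab <- peak_table(flt$too_short$chrom, flt$too_short$start,
                            flt$too_short$end, motif = "too short")
    tab <- rbind(tab, short_tab)
    tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
    rownames(tab) <- NULL
    class(tab) <- c("peak_table", "data.frame")
  }

  list(peak_table = tab, peaks = kept, too_short = flt$too_short,
       windows_model = model, motif = motif, tss_distances = tss_dist,
       log = list(config = config, lambda_r = lam_r, lambda_n = lam_n,
                  p0 = model$p0,
                  d0 = if (!is.null(config$d0)) config$d0 else model$d0,
                  n_windows = nrow(windows),
                  n_excluded = sum(windows$excluded),
                  n_significant = sum(windows$significant),
                  locfdr_table = model$table))
}
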