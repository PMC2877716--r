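#' @useDynLib skelpeak, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# All genomic coordinates in this package are 0-based, half-open (the BED
# convention), both on disk and in memory.

.read_bed_fields <- function(path, min_fields) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L)
    return(list(fields = list(), lineno = integer(0)))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected >= %d fields, got %d",
                 bad[1], path, min_fields, nf[bad[1]]))
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends) | starts < 0 | ends < starts)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: bad interval coordinates",
                 bad[1], path))
  list(chrom = vapply(fields, `[[`, "", 1L), start = starts, end = ends,
       fields = fields, nf = nf)
}

#' Read mapped sequencing tags from a BED file
#'
#' Each BED interval is reduced to the 5' position of the read it represents:
#' the interval start for plus-strand reads and `end - 1` for minus-strand
#' reads (0-based, half-open input). Read length plays no further role; the
#' window statistic downstream counts 5' positions, not coverage. Duplicate
#' tags are kept as-is (no PCR-duplicate collapsing).
#'
#' @param path BED3+ file; column 6, when present, is the strand.
#' @param sample sample label, conventionally `"WT"` or `"KO"`.
#' @param annotation optional [read_annotation()] object; when supplied,
#'   chromosome names and bounds are validated against it.
#' @return a `tag_track`: data.frame with columns `chrom`, `pos`, `strand`,
#'   sorted by chromosome then position, with a `sample` attribute.
#' @export
read_tags <- function(path, sample = "WT", annotation = NULL) {
  bed <- .read_bed_fields(path, 3L)
  if (length(bed$chrom) == 0L) {
    tr <- data.frame(chrom = character(0), pos = integer(0),
                     strand = character(0))
    return(tag_track(tr, sample))
  }
  strand <- vapply(bed$fields, function(f) {
    if (length(f) >= 6L) f[[6L]] else "+"
  }, character(1))
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad))
    stop(sprintf("malformed line %d in %s: bad strand '%s'",
                 bad[1], path, strand[bad[1]]))
  strand[strand == "."] <- "+"
  pos <- ifelse(strand == "+", bed$start, bed$end - 1L)
  tr <- data.frame(chrom = bed$chrom, pos = as.integer(pos), strand = strand)
  tr <- tr[order(tr$chrom, tr$pos), , drop = FALSE]
  rownames(tr) <- NULL
  tt <- tag_track(tr, sample)
  if (!is.null(annotation)) .validate_tags(tt, annotation)
  tt
}

tag_track <- function(df, sample) {
  structure(df, sample = sample, class = c("tag_track", "data.frame"))
}

.validate_tags <- function(tags, annotation) {
  unknown <- setdiff(unique(tags$chrom), names(annotation$chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome(s) in tag file: ", paste(unknown, collapse = ", "))
  len <- annotation$chrom_sizes[tags$chrom]
  if (any(tags$pos < 0 | tags$pos >= len))
    stop("tag position outside chromosome bounds")
  invisible(tags)
}

#' Read genome annotation: chromosome sizes, TSS records, repeat mask
#'
#' The repeat mask is normalized on read: intervals are sorted and
#' overlapping/adjacent intervals are merged. TSS files are BED-like with the
#' TSS point at the interval start, the gene symbol in column 4 and the
#' strand in column 6; records are kept in input order.
#'
#' @param chrom_sizes_path two-column table (chromosome, length in bp).
#' @param tss_path optional BED file of TSS points.
#' @param mask_path optional BED3 file of repeat-masked intervals.
#' @return a `genome_annotation` list with elements `chrom_sizes` (named
#'   integer vector), `tss` (data.frame chrom/pos/strand/gene) and `mask`
#'   (data.frame chrom/start/end, sorted and non-overlapping).
#' @export
read_annotation <- function(chrom_sizes_path, tss_path = NULL,
                            mask_path = NULL) {
  sz <- utils::read.table(chrom_sizes_path, header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (any(sz$length <= 0)) stop("chromosome lengths must be positive")
  sizes <- stats::setNames(sz$length, sz$chrom)

  tss <- data.frame(chrom = character(0), pos = integer(0),
                    strand = character(0), gene = character(0))
  if (!is.null(tss_path)) {
    bed <- .read_bed_fields(tss_path, 4L)
    if (length(bed$chrom)) {
      strand <- vapply(bed$fields, function(f) {
        if (length(f) >= 6L) f[[6L]] else "+"
      }, character(1))
      if (!all(strand %in% c("+", "-")))
        stop("TSS strand must be '+' or '-'")
      tss <- data.frame(chrom = bed$chrom, pos = bed$start, strand = strand,
                        gene = vapply(bed$fields, `[[`, "", 4L))
      unknown <- setdiff(unique(tss$chrom), names(sizes))
      if (length(unknown))
        stop("unknown chromosome(s) in TSS file: ",
             paste(unknown, collapse = ", "))
      if (any(tss$pos >= sizes[tss$chrom] | tss$pos < 0))
        stop("TSS position outside chromosome bounds")
    }
  }

  mask <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
  if (!is.null(mask_path)) {
    bed <- .read_bed_fields(mask_path, 3L)
    if (length(bed$chrom)) {
      unknown <- setdiff(unique(bed$chrom), names(sizes))
      if (length(unknown))
        stop("unknown chromosome(s) in mask file: ",
             paste(unknown, collapse = ", "))
      if (any(bed$end > sizes[bed$chrom]))
        stop("mask interval outside chromosome bounds")
      parts <- lapply(split(seq_along(bed$chrom), bed$chrom), function(i) {
        ir <- IRanges::reduce(IRanges::IRanges(bed$start[i] + 1L, bed$end[i]))
        data.frame(chrom = bed$chrom[i][1],
                   start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
      })
      mask <- do.call(rbind, parts)
      rownames(mask) <- NULL
    }
  }

  structure(list(chrom_sizes = sizes, tss = tss, mask = mask),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome annotation: %d chromosome(s), %d TSS record(s), %d mask interval(s)\n",
    length(x$chrom_sizes), nrow(x$tss), nrow(x$mask)))
  invisible(x)
}

.peak_table_cols <- c("chrom", "start", "end", "gene", "motif", "affinity")

#' Assemble a peak table
#'
#' One record per called peak: genomic interval, nearest gene symbol (or
#' empty), best motif site (or the flags `"none"` / `"too short"`), and the
#' High/Medium/Low affinity category (or empty).
#'
#' @param chrom,start,end peak coordinates (0-based, half-open).
#' @param gene,motif,affinity character annotations; default empty.
#' @return a `peak_table` data.frame.
#' @export
peak_table <- function(chrom = character(0), start = integer(0),
                       end = integer(0), gene = "", motif = "",
                       affinity = "") {
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0L) n <- 0L
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   gene = rep_len(as.character(gene), n),
                   motif = rep_len(as.character(motif), n),
                   affinity = rep_len(as.character(affinity), n))
  if (any(df$start >= df$end)) stop("peak start must be < end")
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Write / read a peak table as TSV
#'
#' Tab-separated with a header row; `write_peak_table()` followed by
#' [read_peak_table()] is the identity, including empty fields and the
#' `"none"` / `"too short"` motif flags.
#'
#' @param peaks a [peak_table()].
#' @param path output file.
#' @export
write_peak_table <- function(peaks, path) {
  stopifnot(all(.peak_table_cols %in% names(peaks)))
  utils::write.table(as.data.frame(peaks)[, .peak_table_cols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", comment.char = "")
  missing <- setdiff(.peak_table_cols, names(df))
  if (length(missing))
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "))
  peak_table(df$chrom, as.integer(df$start), as.integer(df$end),
             df$gene, df$motif, df$affinity)
}

#' Read / write plain sequence lists (one sequence per line)
#'
#' The interchange format for SELEX oligo pools.
#'
#' @param path text file, one nucleotide sequence per line.
#' @return character vector of uppercase sequences.
#' @export
read_sequence_list <- function(path) {
  x <- readLines(path)
  x <- toupper(trimws(x[nzchar(trimws(x))]))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop("non-nucleotide characters in sequence list: line ",
                     which(bad)[1])
  x
}

#' @rdname read_sequence_list
#' @param seqs character vector of sequences.
#' @export
write_sequence_list <- function(seqs, path) {
  writeLines(as.character(seqs), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning uppercase
#' sequences named by the first word of each header.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract peak sequences from a genome
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genome a [Biostrings::DNAStringSet].
#' @return character vector of peak sequences.
#' @export
peak_sequences <- function(peaks, genome) {
  unknown <- setdiff(unique(peaks$chrom), names(genome))
  if (length(unknown))
    stop("chromosome(s) absent from genome: ", paste(unknown, collapse = ", "))
  vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = peaks$start[i] + 1L,
                                    end = peaks$end[i]))
  }, character(1))
}

#' Read an expression sample table
#'
#' TSV with columns `animal`, `genotype` (WT/KO), `target`, `reference`
#' (the normalization gene measurement, e.g. Gapdh; must be positive).
#'
#' @param path TSV file with header.
#' @return data.frame of expression samples.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("animal", "genotype", "target", "reference"), names(df))
  if (length(missing))
    stop("expression table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(df$reference <= 0)) stop("reference measurements must be positive")
  df
}
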