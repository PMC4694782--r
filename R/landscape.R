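# Peak enrichment and the chromatin landscape around binding sites:
# strand-aware promoter windows, promoter / enhancer / unmarked-distal
# classification, and chromatin-mark overlap summaries.

PEAK_CLASSES <- c("PROMOTER", "ENHANCER", "UNMARKED_DISTAL")

#' Reads per million of library reads
#'
#' @param reads non-negative read count(s) on a region.
#' @param libsize positive total library size(s).
#' @return reads * 1e6 / libsize.
#' @export
normalized_count <- function(reads, libsize) {
  if (any(libsize <= 0)) stop("libsize must be > 0")
  if (any(reads < 0)) stop("reads must be >= 0")
  reads * 1e6 / libsize
}

#' Background-subtracted peak enrichment
#'
#' log2 of the difference between the ChIP and input signals on the peak,
#' both expressed as reads per million of library reads:
#' `log2(chip_rpm - input_rpm)`. When the difference is non-positive the
#' enrichment is undefined (NA) and the peak is excluded from rankings.
#'
#' @param peaks a `peak_set` with chip/input counts and library sizes, or
#'   NULL to use the scalar arguments.
#' @param chip_count,input_count,chip_libsize,input_libsize scalar/vector
#'   alternative interface.
#' @return with `peaks`, the peak set with its `enrichment` column filled;
#'   otherwise a numeric vector (NA where undefined).
#' @export
peak_enrichment <- function(peaks = NULL, chip_count, input_count,
                            chip_libsize, input_libsize) {
  if (!is.null(peaks)) {
    e <- peak_enrichment(NULL, peaks$chip_count, peaks$input_count,
                         peaks$chip_libsize, peaks$input_libsize)
    peaks$enrichment <- e
    return(peaks)
  }
  d <- normalized_count(chip_count, chip_libsize) -
    normalized_count(input_count, input_libsize)
  ifelse(d > 0, log2(pmax(d, .Machine$double.xmin)), NA_real_)
}

#' Strand-aware promoter window around a TSS
#'
#' For a + strand gene the window is `[tss - up, tss + down)`; for a -
#' strand gene `[tss - down, tss + up)`. Coordinates are clamped to
#' `[0, chrom_len)`. Defaults give the -5/+2 kb promoter definition.
#'
#' @param tss 0-based TSS position(s).
#' @param strand "+" or "-" (vectorised).
#' @param up,down bp upstream / downstream of the TSS (defaults 5000/2000).
#' @param chrom_len chromosome length(s) for clamping.
#' @return data frame with columns `start`, `end` (0-based half-open).
#' @export
promoter_window <- function(tss, strand, up = 5000L, down = 2000L,
                            chrom_len) {
  if (any(tss < 0 | tss >= chrom_len)) {
    stop("tss outside chromosome [0, chrom_len)")
  }
  plus <- strand == "+"
  start <- ifelse(plus, tss - up, tss - down)
  end <- ifelse(plus, tss + down, tss + up)
  data.frame(start = pmax(0L, as.integer(start)),
             end = pmin(as.integer(chrom_len), as.integer(end)))
}

#' Promoter windows for a gene table
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `tss`,
#'   `strand`.
#' @param chrom_lens named vector of chromosome lengths.
#' @inheritParams promoter_window
#' @return a `peak_set` of promoter windows named by gene_id.
#' @export
promoter_windows <- function(genes, chrom_lens, up = 5000L, down = 2000L) {
  len <- chrom_lens[genes$chrom]
  if (anyNA(len)) stop("gene chromosome missing from chrom_lens")
  w <- promoter_window(genes$tss, genes$strand, up, down, len)
  peak_set(genes$chrom, w$start, w$end, name = genes$gene_id,
           strand = genes$strand, label = "promoters")
}

#' Classify binding sites as promoter, enhancer or unmarked distal
#'
#' A peak overlapping any promoter window is PROMOTER; otherwise a peak
#' overlapping any H3K4me1 peak is ENHANCER; everything else is
#' UNMARKED_DISTAL. Overlap uses the whole peak interval by default
#' (`summit_only = TRUE` restricts it to the 1-bp summit).
#'
#' @param peaks a `peak_set`.
#' @param promoters a `peak_set` of promoter windows.
#' @param marks named list of `peak_set`s; must contain `H3K4me1`.
#' @param min_bp minimum overlap in bp.
#' @param summit_only classify by the summit base only.
#' @return list with `classes` (data frame `peak_name`, `class`) and
#'   `counts` (named vector over the three classes, summing to the number
#'   of peaks).
#' @export
classify_peaks <- function(peaks, promoters, marks, min_bp = 1L,
                           summit_only = FALSE) {
  if (!"H3K4me1" %in% names(marks)) {
    stop("marks must contain an H3K4me1 peak set")
  }
  q <- peaks
  if (summit_only && nrow(peaks) > 0L) {
    s <- peaks$start + peaks$summit_offset
    q <- peak_set(peaks$chrom, s, s + 1L, name = peaks$name)
  }
  lev <- unique(c(q$chrom, promoters$chrom, marks$H3K4me1$chrom))
  gr <- peaks_to_granges(q, lev)
  in_prom <- GenomicRanges::countOverlaps(
    gr, peaks_to_granges(promoters, lev), minoverlap = min_bp) > 0L
  in_k4me1 <- GenomicRanges::countOverlaps(
    gr, peaks_to_granges(marks$H3K4me1, lev), minoverlap = min_bp) > 0L
  cls <- ifelse(in_prom, "PROMOTER",
                ifelse(in_k4me1, "ENHANCER", "UNMARKED_DISTAL"))
  counts <- vapply(PEAK_CLASSES, function(k) sum(cls == k), 0L)
  list(classes = data.frame(peak_name = peaks$name, class = cls,
                            stringsAsFactors = FALSE),
       counts = counts)
}

#' Percentage of peaks per class overlapping each chromatin mark
#'
#' @param peaks a `peak_set`.
#' @param classes data frame `peak_name`, `class` from [classify_peaks()].
#' @param marks named list of `peak_set`s.
#' @param min_bp minimum overlap in bp.
#' @return matrix class x mark of percentages (0-100).
#' @export
mark_overlap_summary <- function(peaks, classes, marks, min_bp = 1L) {
  cls <- classes$class[match(peaks$name, classes$peak_name)]
  out <- matrix(NA_real_, length(PEAK_CLASSES), length(marks),
                dimnames = list(PEAK_CLASSES, names(marks)))
  for (k in PEAK_CLASSES) {
    sub <- peaks[!is.na(cls) & cls == k, , drop = FALSE]
    for (m in names(marks)) {
      out[k, m] <- if (nrow(sub) == 0L) NA_real_ else
        100 * overlap_fraction(sub, marks[[m]], min_bp)
    }
  }
  out
}

#' Percentage of peaks per chromatin class carrying the motif
#'
#' @param classes data frame `peak_name`, `class` from [classify_peaks()].
#' @param motif_classes data frame `peak_name`, `motif_class` from
#'   [classify_hits()].
#' @return named vector over chromatin classes: percent of peaks whose
#'   motif class is not NO_MOTIF.
#' @export
motif_by_class <- function(classes, motif_classes) {
  if (!setequal(classes$peak_name, motif_classes$peak_name)) {
    stop("classes and motif_classes must cover the same peaks")
  }
  mc <- motif_classes$motif_class[match(classes$peak_name,
                                        motif_classes$peak_name)]
  vapply(PEAK_CLASSES, function(k) {
    sel <- classes$class == k
    if (!any(sel)) return(NA_real_)
    100 * mean(mc[sel] != "NO_MOTIF")
  }, numeric(1))
}
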