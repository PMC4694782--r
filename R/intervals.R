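# Genomic intervals and peak sets. Coordinates are 0-based half-open
# (BED convention) everywhere inside the package; overlap arithmetic is
# delegated to IRanges/GenomicRanges.

#' Construct a peak set
#'
#' A `peak_set` is a data frame of called binding sites with 0-based
#' half-open coordinates, a summit, optional per-library read counts and a
#' derived enrichment (NA until computed, or where the background-subtracted
#' signal is non-positive).
#'
#' @param chrom,start,end,name,score,strand BED-style fields (start/end
#'   0-based half-open; strand in +/-/.).
#' @param summit_offset summit position relative to `start` (>= 0,
#'   < end - start); defaults to the interval midpoint.
#' @param chip_count,input_count,chip_libsize,input_libsize per-peak read
#'   counts and library totals for the ChIP and input libraries.
#' @param enrichment precomputed enrichment values (optional).
#' @param label sample identity of the set (e.g. cell type x treatment).
#' @return a data frame of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end,
                     name = sprintf("peak_%d", seq_along(start)),
                     score = 0, strand = ".",
                     summit_offset = NULL,
                     chip_count = NA_integer_, input_count = NA_integer_,
                     chip_libsize = NA_integer_, input_libsize = NA_integer_,
                     enrichment = NA_real_, label = "") {
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  start <- as.integer(start); end <- as.integer(end)
  if (length(end) != n) stop("start and end must have equal length")
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  bad <- which(!(start >= 0L & start < end))
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) at record ", bad[1])
  }
  if (is.null(summit_offset)) summit_offset <- (end - start) %/% 2L
  summit_offset <- as.integer(summit_offset)
  if (any(summit_offset < 0L | start + summit_offset >= end)) {
    stop("summit_offset must satisfy 0 <= summit_offset < end - start")
  }
  if (anyDuplicated(name)) stop("peak names must be unique within a set")
  df <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    name = as.character(name),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    summit_offset = summit_offset,
    chip_count = rep_len(as.integer(chip_count), n),
    input_count = rep_len(as.integer(input_count), n),
    chip_libsize = rep_len(as.double(chip_libsize), n),
    input_libsize = rep_len(as.double(input_libsize), n),
    enrichment = rep_len(as.numeric(enrichment), n),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("peak_set", "data.frame"), label = label)
}

# seqlevels must cover both sets being compared, otherwise ranges on
# chromosomes private to one set make the overlap engine refuse to merge
peaks_to_granges <- function(ps, seqlevels = unique(ps$chrom)) {
  if (length(seqlevels) == 0L) seqlevels <- "chrNA"
  GenomicRanges::GRanges(
    seqnames = factor(ps$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = ps$start + 1L, end = ps$end)
  )
}

#' Read a BED or narrowPeak file into a peak set
#'
#' BED input (>= 3 columns) sets the summit to the interval midpoint;
#' narrowPeak input (10 columns) takes the summit offset from column 10
#' (-1 meaning unknown falls back to the midpoint). Malformed lines
#' (non-integer coordinates, start >= end, too few fields) raise an error
#' naming the line.
#'
#' @param path input file.
#' @param format `"bed"` or `"narrowPeak"`.
#' @param label label stored on the returned set.
#' @return a `peak_set` (rows in file order).
#' @export
read_regions <- function(path, format = c("narrowPeak", "bed"), label = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  need <- if (format == "narrowPeak") 10L else 3L
  if (length(lines) == 0L) {
    return(peak_set(character(0), integer(0), integer(0),
                    name = character(0), label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_int <- function(x, what, i) {
    v <- suppressWarnings(as.integer(x))
    if (is.na(v)) stop(sprintf("line %d: non-integer %s '%s' in %s",
                               i, what, x, path))
    v
  }
  n <- length(fields)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  name <- character(n); score <- numeric(n); strand <- character(n)
  summit <- integer(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < need) {
      stop(sprintf("line %d: expected >= %d tab-separated fields, got %d in %s",
                   i, need, length(f), path))
    }
    chrom[i] <- f[1]
    start[i] <- parse_int(f[2], "start", i)
    end[i] <- parse_int(f[3], "end", i)
    if (start[i] >= end[i]) {
      stop(sprintf("line %d: start (%d) >= end (%d) in %s",
                   i, start[i], end[i], path))
    }
    name[i] <- if (length(f) >= 4L && nzchar(f[4]) && f[4] != ".")
      f[4] else sprintf("peak_%d", i)
    score[i] <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else 0
    strand[i] <- if (length(f) >= 6L) f[6] else "."
    if (format == "narrowPeak") {
      sm <- parse_int(f[10], "summit offset", i)
      summit[i] <- if (sm >= 0L) sm else (end[i] - start[i]) %/% 2L
    } else {
      summit[i] <- (end[i] - start[i]) %/% 2L
    }
  }
  score[is.na(score)] <- 0
  if (anyDuplicated(name)) name <- make.unique(name, sep = "_")
  peak_set(chrom, start, end, name = name, score = score, strand = strand,
           summit_offset = summit, label = label)
}

#' Write a peak set as BED6 or narrowPeak
#'
#' @param ps a `peak_set`.
#' @param path output file.
#' @param format `"bed"` (BED6) or `"narrowPeak"` (10 columns; the
#'   enrichment goes in signalValue, NA written as 0).
#' @export
write_regions <- function(ps, path, format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  strand <- ifelse(ps$strand %in% c("+", "-"), ps$strand, ".")
  if (format == "bed") {
    df <- data.frame(ps$chrom, ps$start, ps$end, ps$name, ps$score, strand)
  } else {
    sig <- ifelse(is.na(ps$enrichment), 0, ps$enrichment)
    df <- data.frame(ps$chrom, ps$start, ps$end, ps$name, ps$score, strand,
                     sig, -1, -1, ps$summit_offset)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fraction of peaks in one set overlapping another
#'
#' Peak-wise: a peak of `a` counts once however many peaks of `b` it
#' touches. Overlap uses half-open interval arithmetic and requires at
#' least `min_bp` shared bases.
#'
#' @param a,b `peak_set` objects on the same chromosome namespace.
#' @param min_bp minimum shared bases (default 1).
#' @return fraction in [0, 1]; an empty `a` gives 0.
#' @export
overlap_fraction <- function(a, b, min_bp = 1L) {
  if (nrow(a) == 0L) return(0)
  if (nrow(b) == 0L) return(0)
  lev <- unique(c(a$chrom, b$chrom))
  hits <- GenomicRanges::countOverlaps(
    peaks_to_granges(a, lev), peaks_to_granges(b, lev),
    minoverlap = min_bp
  )
  mean(hits > 0L)
}

#' Per-quintile overlap of one peak set with another
#'
#' Ranks the peaks of `a` by enrichment (ascending; ties broken by peak
#' name), partitions them into 5 bins of near-equal size (any remainder
#' goes to the lowest bins), and reports the fraction of each bin
#' overlapping `b`. Q5 is the highest-enrichment quintile.
#'
#' @param a `peak_set` with defined (non-NA) enrichment for every peak.
#' @param b `peak_set` to overlap against.
#' @param min_bp minimum shared bases.
#' @return numeric vector of length 5, names Q1..Q5.
#' @export
quintile_overlap <- function(a, b, min_bp = 1L) {
  n <- nrow(a)
  if (n < 5L) stop("need at least 5 peaks to form quintiles, got ", n)
  if (anyNA(a$enrichment)) stop("all peaks in a must have defined enrichment")
  ord <- order(a$enrichment, a$name)
  base <- n %/% 5L
  rem <- n %% 5L
  sizes <- rep(base, 5L)
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin <- rep(1:5, times = sizes)
  out <- vapply(1:5, function(q) {
    idx <- ord[bin == q]
    overlap_fraction(a[idx, , drop = FALSE], b, min_bp)
  }, numeric(1))
  names(out) <- paste0("Q", 1:5)
  out
}
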