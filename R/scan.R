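# Scanning summit-flanking sequence with the dimeric spacer-variant PWM
# array. Because spacer columns equal the background, every variant's score
# is the sum of the two half-site scores and all variants share one null
# score distribution, so a single DP table serves the whole array.

half_site_scores <- function(codes, lo) {
  w <- ncol(lo)
  m <- length(codes) - w + 1L
  if (m < 1L) return(numeric(0))
  s <- numeric(m)
  for (k in seq_len(w)) {
    s <- s + lo[cbind(codes[k:(k + m - 1L)] + 1L, k)]
  }
  s
}

# Scores one strand against all spacer variants. Two parallel scores are
# kept per position: the float log-odds sum (reported) and the sum of the
# per-column lattice-rounded log-odds (`idx`, in granularity units), which
# indexes the DP null distribution so hit p-values use exactly the
# discretisation the DP used.
scan_one_strand <- function(codes, model, L, granularity) {
  lo1 <- pwm_lodds(model$half1)
  lo2 <- pwm_lodds(model$half2)
  h1 <- half_site_scores(codes, lo1)
  h2 <- half_site_scores(codes, lo2)
  h1i <- half_site_scores(codes, round(lo1 / granularity))
  h2i <- half_site_scores(codes, round(lo2 / granularity))
  out <- vector("list", model$max_spacer + 1L)
  for (s in 0:model$max_spacer) {
    w <- 20L + s
    m <- L - w + 1L
    if (m < 1L) next
    j <- (11L + s):(10L + s + m)
    out[[s + 1L]] <- data.frame(pos = seq_len(m), spacer = s,
                                score = h1[seq_len(m)] + h2[j],
                                idx = h1i[seq_len(m)] + h2i[j])
  }
  do.call(rbind, out)
}

#' Scan a summit-flanking window for the best dimeric motif hit
#'
#' Scores every position of `seq` on both strands against all spacer
#' variants of `model`, converts scores to exact match p-values, and
#' returns the hit with the lowest p-value among those below `threshold`.
#' Ties are broken by smaller spacer, then smaller offset, then + strand.
#'
#' @param seq window sequence (typically the 600 bases centred on a peak
#'   summit; may be shorter at chromosome edges) over {A,C,G,T,N}.
#' @param model a `spaced_pwm`.
#' @param threshold per-match p-value cutoff (strict `<`); default 1e-4.
#' @param granularity lattice width for the p-value DP.
#' @param report_all if TRUE, return all passing hits (sorted) instead of
#'   the single best one.
#' @param dist optional precomputed null score distribution
#'   (from [pwm_score_dist()] on any variant); computed if NULL.
#' @return a list with elements `offset` (0-based start of the match in the
#'   window, plus-strand coordinates), `strand`, `spacer`, `score`,
#'   `pvalue`, `matched_seq` (motif-oriented); or NULL when no position
#'   passes the threshold. With `report_all = TRUE`, a data frame.
#' @export
scan_window <- function(seq, model, threshold = 1e-4, granularity = 1e-4,
                        report_all = FALSE, dist = NULL) {
  stopifnot(inherits(model, "spaced_pwm"))
  codes_f <- encode_seq(seq)
  L <- length(codes_f)
  if (is.null(dist)) dist <- pwm_score_dist(model$variants[["0"]], granularity)
  empty <- if (report_all) {
    data.frame(offset = integer(0), strand = character(0),
               spacer = integer(0), score = numeric(0),
               pvalue = numeric(0), matched_seq = character(0))
  } else NULL
  if (L < 20L) return(empty)
  rc <- revcomp(seq)
  codes_r <- encode_seq(rc)

  fwd <- scan_one_strand(codes_f, model, L, granularity)
  rev_ <- scan_one_strand(codes_r, model, L, granularity)
  fwd$strand <- "+"
  # a hit starting at rc position j with width w covers original
  # positions (L - j - w + 2) .. (L - j + 1), 1-based
  rev_$strand <- "-"
  rev_$pos <- L - rev_$pos - (20L + rev_$spacer) + 2L
  hits <- rbind(fwd, rev_)
  hits$pvalue <- score_dist_tail_idx(dist, hits$idx - dist$origin + 1L)
  hits <- hits[hits$pvalue < threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  ord <- order(hits$pvalue, hits$spacer, hits$pos,
               match(hits$strand, c("+", "-")))
  hits <- hits[ord, , drop = FALSE]
  hits$offset <- hits$pos - 1L
  w <- 20L + hits$spacer
  hits$matched_seq <- substr(rep(seq, nrow(hits)), hits$pos, hits$pos + w - 1L)
  flip <- hits$strand == "-"
  hits$matched_seq[flip] <- vapply(hits$matched_seq[flip], revcomp, "")
  hits <- hits[, c("offset", "strand", "spacer", "score", "pvalue",
                   "matched_seq")]
  rownames(hits) <- NULL
  if (report_all) return(hits)
  as.list(hits[1L, ])
}

#' Scan every peak of a peak set for its best motif hit
#'
#' Extracts the `2*flank` bases centred on each peak summit from the genome
#' (clamped at chromosome edges) and runs [scan_window()].
#'
#' @param peaks a `peak_set`.
#' @param genome named character vector of chromosome sequences
#'   (see [read_genome()]).
#' @param model a `spaced_pwm`.
#' @param flank half-window in bp (default 300, i.e. 600 bases flanking
#'   the summit).
#' @inheritParams scan_window
#' @return data frame with one row per peak: `peak_name`, `offset`,
#'   `strand`, `spacer`, `score`, `pvalue`, `matched_seq` (NA fields when
#'   no hit passed).
#' @export
scan_peaks <- function(peaks, genome, model, flank = 300L,
                       threshold = 1e-4, granularity = 1e-4) {
  dist <- pwm_score_dist(model$variants[["0"]], granularity)
  n <- nrow(peaks)
  res <- data.frame(
    peak_name = peaks$name, offset = NA_integer_, strand = NA_character_,
    spacer = NA_integer_, score = NA_real_, pvalue = NA_real_,
    matched_seq = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome)) {
      stop("chromosome not in genome: ", chrom)
    }
    summit1 <- peaks$start[i] + peaks$summit_offset[i] + 1L  # 1-based
    win <- extract_window(genome[[chrom]], summit1, flank)
    hit <- scan_window(win, model, threshold, granularity, dist = dist)
    if (!is.null(hit)) {
      res$offset[i] <- hit$offset
      res$strand[i] <- hit$strand
      res$spacer[i] <- hit$spacer
      res$score[i] <- hit$score
      res$pvalue[i] <- hit$pvalue
      res$matched_seq[i] <- hit$matched_seq
    }
  }
  res
}

#' Motif class per peak and class frequencies
#'
#' Assigns each peak one of three motif classes from its best hit:
#' `UNSPLIT` (spacer 0), `SPACED` (spacer 1+), `NO_MOTIF` (no hit below
#' the threshold).
#'
#' @param hits data frame as returned by [scan_peaks()] (one row per peak;
#'   `spacer` NA when there was no hit).
#' @return list with `classes` (data frame `peak_name`, `motif_class`) and
#'   `frequencies` (named fractions over NO_MOTIF/UNSPLIT/SPACED, summing
#'   to 1).
#' @export
classify_hits <- function(hits) {
  cls <- ifelse(is.na(hits$spacer), "NO_MOTIF",
                ifelse(hits$spacer == 0L, "UNSPLIT", "SPACED"))
  classes <- data.frame(peak_name = hits$peak_name, motif_class = cls,
                        stringsAsFactors = FALSE)
  n <- nrow(hits)
  freq <- c(NO_MOTIF = sum(cls == "NO_MOTIF"),
            UNSPLIT = sum(cls == "UNSPLIT"),
            SPACED = sum(cls == "SPACED")) / max(n, 1L)
  list(classes = classes, frequencies = freq)
}

#' Distribution of spacer lengths among spaced hits
#'
#' @param hits data frame from [scan_peaks()].
#' @param max_spacer largest spacer length tracked (default 15).
#' @return integer vector of counts named "1".."max_spacer"; sums to the
#'   number of SPACED hits.
#' @export
spacer_distribution <- function(hits, max_spacer = 15L) {
  sp <- as.integer(hits$spacer)
  sp <- sp[!is.na(sp) & sp >= 1L]
  counts <- tabulate(sp, nbins = max_spacer)
  names(counts) <- as.character(seq_len(max_spacer))
  counts
}

#' Pairwise Student's t comparison of per-class value distributions
#'
#' Two-sample t-tests (pooled variance by default, Welch optionally) for
#' every pair of groups, plus box-plot style per-group summaries. Used to
#' compare peak enrichment across motif classes and fold changes across
#' regulatory categories.
#'
#' @param values_by_class named list of numeric vectors, each of length
#'   >= 2.
#' @param welch use Welch's unequal-variance t instead of the pooled test.
#' @return list with `tests` (data frame: group1, group2, t, df, pvalue)
#'   and `summaries` (data frame: class, n, mean, q1, median, q3).
#' @export
group_compare <- function(values_by_class, welch = FALSE) {
  if (is.null(names(values_by_class)) ||
      any(!nzchar(names(values_by_class)))) {
    stop("values_by_class must be a named list")
  }
  sizes <- vapply(values_by_class, length, 0L)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 values; offending: ",
         paste(names(values_by_class)[sizes < 2L], collapse = ", "))
  }
  nms <- names(values_by_class)
  pairs <- utils::combn(nms, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    x <- values_by_class[[pairs[1, j]]]
    y <- values_by_class[[pairs[2, j]]]
    if (welch) {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      t <- unname(tt$statistic); df <- unname(tt$parameter)
      p <- tt$p.value
    } else {
      n1 <- length(x); n2 <- length(y)
      df <- n1 + n2 - 2
      s2p <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
      se <- sqrt(s2p * (1 / n1 + 1 / n2))
      d <- mean(x) - mean(y)
      if (se == 0) {          # both groups constant
        t <- if (d == 0) 0 else sign(d) * Inf
        p <- if (d == 0) 1 else 0
      } else {
        t <- d / se
        p <- 2 * stats::pt(-abs(t), df)
      }
    }
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               t = t, df = df, pvalue = p, stringsAsFactors = FALSE)
  }))
  summaries <- do.call(rbind, lapply(nms, function(g) {
    v <- values_by_class[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(class = g, n = length(v), mean = mean(v),
               q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  list(tests = tests, summaries = summaries)
}
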