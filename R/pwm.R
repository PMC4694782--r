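#' Position weight matrix constructor
#'
#' Builds a PWM object from a matrix of per-position base probabilities.
#' Rows are motif positions, columns are the bases A, C, G, T. All
#' probabilities must be strictly positive (apply a pseudocount first when
#' deriving the matrix from counts; see [pwm_from_counts()]) and each row
#' must sum to one.
#'
#' @param probs numeric matrix, width x 4, columns in A,C,G,T order.
#' @param background length-4 base frequency vector summing to 1
#'   (default uniform).
#' @param pseudocount the pseudocount that was applied upstream; recorded
#'   for provenance only.
#' @return an object of class `pwm` with elements `probs`, `width`,
#'   `background`, `pseudocount`.
#' @export
new_pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("probs must have 4 columns (A,C,G,T)")
  if (any(probs <= 0)) stop("all PWM entries must be > 0 (apply a pseudocount)")
  if (any(abs(rowSums(probs) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("background must be 4 positive frequencies summing to 1")
  }
  colnames(probs) <- BASES
  structure(
    list(probs = probs, width = nrow(probs),
         background = as.numeric(background), pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM of width %d (consensus %s), IC %.2f bits\n",
              x$width, pwm_consensus(x), information_content(x)))
  invisible(x)
}

#' Build a PWM from aligned site counts
#'
#' @param counts width x 4 matrix of base counts at each position.
#' @param pseudocount value added to every cell before normalisation
#'   (default 0.1).
#' @param background background base frequencies.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.1,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts) + pseudocount
  new_pwm(counts / rowSums(counts), background, pseudocount)
}

#' Estimate background base frequencies from sequences
#'
#' Counts A/C/G/T over the supplied sequences (N ignored).
#' @param seqs character vector of DNA sequences.
#' @export
background_from_seqs <- function(seqs) {
  codes <- unlist(lapply(seqs, encode_seq))
  tab <- tabulate(codes, nbins = 4L)
  if (sum(tab) == 0) stop("no A/C/G/T bases in input")
  tab / sum(tab)
}

# log2-odds lookup, 5 x width: row 1 is the N code (contributes 0),
# rows 2..5 are A,C,G,T.
pwm_lodds <- function(pwm) {
  lo <- t(log2(pwm$probs / matrix(pwm$background, pwm$width, 4, byrow = TRUE)))
  rbind(N = 0, lo)
}

#' Majority-base consensus string of a PWM
#' @param pwm a `pwm` object.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$probs, 1L, which.max)], collapse = "")
}

#' Information content of a PWM in bits
#'
#' Sum over columns of `2 + sum(p * log2 p)` (uniform-background
#' convention).
#' @param pwm a `pwm` object.
#' @export
information_content <- function(pwm) {
  sum(2 + rowSums(pwm$probs * log2(pwm$probs)))
}

#' Log-odds score of a sequence against a PWM
#'
#' Sum over positions of log2(p(base)/background(base)), in bits. The
#' ambiguity code N contributes 0 (background-equivalent), so N-rich
#' sequence can never score above a fully matched one.
#'
#' @param pwm a `pwm` object.
#' @param seq character string, same length as the PWM width, over
#'   {A,C,G,T,N}.
#' @return score in bits.
#' @export
log_odds_score <- function(pwm, seq) {
  codes <- encode_seq(seq)
  if (length(codes) != pwm$width) {
    stop(sprintf("sequence length %d != PWM width %d",
                 length(codes), pwm$width))
  }
  lo <- pwm_lodds(pwm)
  sum(lo[cbind(codes + 1L, seq_len(pwm$width))])
}

#' Discretised null score distribution of a PWM
#'
#' Dynamic programming under the background model: per-column score mass
#' functions (4 points each, rounded to a lattice of bin width
#' `granularity`) are convolved column by column. Useful for precomputing
#' the distribution once when scanning many windows (see the `dist`
#' argument of [scan_window()]).
#'
#' @param pwm a `pwm` object.
#' @param granularity lattice bin width in bits.
#' @return list with `origin` (lattice index of the minimum score),
#'   `probs` (probability per lattice point), `granularity`, `width`.
#' @export
pwm_score_dist <- function(pwm, granularity = 1e-4) {
  stopifnot(granularity > 0)
  lo <- round(log2(pwm$probs /
                     matrix(pwm$background, pwm$width, 4, byrow = TRUE)) /
                granularity)
  bg <- pwm$background
  lo_min <- apply(lo, 1L, min)
  lo_max <- apply(lo, 1L, max)
  origin <- sum(lo_min)
  probs <- numeric(sum(lo_max - lo_min) + 1L)
  probs[1L] <- 1
  cur_len <- 1L
  cur_origin <- 0L
  for (k in seq_len(pwm$width)) {
    span <- lo_max[k] - lo_min[k]
    new_len <- cur_len + span
    acc <- numeric(new_len)
    for (b in 1:4) {
      sh <- lo[k, b] - lo_min[k]
      idx <- (1L + sh):(cur_len + sh)
      acc[idx] <- acc[idx] + probs[seq_len(cur_len)] * bg[b]
    }
    probs <- acc
    cur_len <- new_len
  }
  list(origin = origin, probs = probs, granularity = granularity,
       width = pwm$width)
}

# Upper-tail lookup against a discretised distribution: P(S >= score).
# Scores are measured on the lattice (columns rounded to the nearest bin),
# so the answer is exact under that convention; for a float query s the
# result is bracketed by the exact float tails at s +- width*granularity.
# Queries are clamped into the lattice range, keeping p-values in (0, 1].
score_dist_tail <- function(dist, score) {
  # kept numeric until after clamping: extreme queries would overflow an
  # integer lattice index
  idx <- round(score / dist$granularity) - dist$origin + 1
  score_dist_tail_idx(dist, idx)
}

# Same, but queried directly with lattice indices (origin-based, 1 = min).
score_dist_tail_idx <- function(dist, idx) {
  tail_ge <- rev(cumsum(rev(dist$probs)))
  n <- length(dist$probs)
  tail_ge[pmin(pmax(idx, 1), n)]
}

#' Exact PWM score p-value by dynamic programming
#'
#' Probability that a random sequence drawn i.i.d. from the PWM's
#' background model scores at least `score`. Per-column log-odds scores are
#' discretised on a lattice of width `granularity` and convolved, giving
#' the full null score distribution; the p-value is the upper tail at the
#' query score. Exact up to the discretisation.
#'
#' @param pwm a `pwm` object.
#' @param score query score in bits (may be a vector).
#' @param granularity lattice bin width in bits (default 1e-4).
#' @return p-value(s) in (0, 1].
#' @export
score_pvalue <- function(pwm, score, granularity = 1e-4) {
  dist <- pwm_score_dist(pwm, granularity)
  score_dist_tail(dist, score)
}

#' Dimeric PWM with spacer variants
#'
#' Splits a width-20 PWM into its two decameric half sites and builds the
#' array of spacer variants: for each spacer length s in 0..`max_spacer`,
#' a PWM of width 20+s whose s central columns equal the background
#' distribution (so a spacer base contributes nothing to the score). The
#' s = 0 variant is the unsplit model and equals the input PWM.
#'
#' @param full a `pwm` of width 20 (two decameric half sites).
#' @param max_spacer largest spacer length (default 15).
#' @param background background frequencies for the spacer columns;
#'   defaults to the input PWM's background.
#' @return an object of class `spaced_pwm` with elements `half1`, `half2`,
#'   `variants` (list indexed by spacer 0..max_spacer), `background`.
#' @export
build_spaced_pwm <- function(full, max_spacer = 15L,
                             background = full$background) {
  if (!inherits(full, "pwm")) stop("full must be a pwm object")
  if (full$width != 20L) stop("full PWM must have width 20")
  half1 <- new_pwm(full$probs[1:10, , drop = FALSE], background,
                   full$pseudocount)
  half2 <- new_pwm(full$probs[11:20, , drop = FALSE], background,
                   full$pseudocount)
  variants <- lapply(0:max_spacer, function(s) {
    spacer_cols <- matrix(rep(background, each = s), nrow = s, ncol = 4)
    probs <- rbind(half1$probs, spacer_cols, half2$probs)
    new_pwm(probs, background, full$pseudocount)
  })
  names(variants) <- as.character(0:max_spacer)
  structure(
    list(half1 = half1, half2 = half2, variants = variants,
         max_spacer = as.integer(max_spacer),
         background = as.numeric(background)),
    class = "spaced_pwm"
  )
}

#' @export
print.spaced_pwm <- function(x, ...) {
  cat(sprintf("Dimeric PWM, half sites %s / %s, spacers 0-%d\n",
              pwm_consensus(x$half1), pwm_consensus(x$half2), x$max_spacer))
  invisible(x)
}

#' The bundled p53 response-element PWM
#'
#' A high-information dimeric model of the canonical p53 response element:
#' two decameric half sites, each with consensus RRRCWWGYYY (R = A/G,
#' W = A/T, Y = C/T). Degenerate positions put probability 0.49 on each of
#' the two consensus bases; the invariant C and G positions carry 0.97.
#' Sharp enough that sampled sites rarely carry more than one strong
#' mismatch, i.e. planted sites are recoverable by scanning at the default
#' threshold. Used as the planted motif by the synthetic-data generators
#' and as a sensible default scanning model.
#'
#' @param background background base frequencies.
#' @return a `pwm` of width 20.
#' @export
pwm_p53 <- function(background = rep(0.25, 4)) {
  two <- function(b1, b2) {
    p <- rep(0.01, 4)
    p[match(c(b1, b2), BASES)] <- 0.49
    p
  }
  one <- function(b) {
    p <- rep(0.01, 4)
    p[match(b, BASES)] <- 0.97
    p
  }
  half <- rbind(two("A", "G"), two("A", "G"), two("A", "G"),
                one("C"),
                two("A", "T"), two("A", "T"),
                one("G"),
                two("C", "T"), two("C", "T"), two("C", "T"))
  new_pwm(rbind(half, half), background)
}

#' Build a PWM around a fixed consensus sequence
#'
#' Each column puts probability `p` on the consensus base and spreads the
#' remainder over the other three bases. Unlike the degenerate response
#' element model of [pwm_p53()], the argmax consensus of this PWM is
#' unambiguous, which makes it the right planted model when a recovered
#' consensus is to be compared position by position.
#'
#' @param consensus DNA string over {A,C,G,T}.
#' @param p probability of the consensus base per column (default 0.85).
#' @param background background base frequencies.
#' @export
consensus_pwm <- function(consensus, p = 0.85, background = rep(0.25, 4)) {
  codes <- encode_seq(consensus)
  if (any(codes == 0L)) stop("consensus must not contain N")
  probs <- matrix((1 - p) / 3, length(codes), 4)
  probs[cbind(seq_along(codes), codes)] <- p
  new_pwm(probs, background)
}

#' Write a PWM in MEME minimal motif format
#'
#' @param pwm a `pwm` object.
#' @param path output file.
#' @param name motif name written in the MOTIF line.
#' @param nsites number of contributing sites recorded in the header.
#' @export
write_meme <- function(pwm, path, name = "motif_1", nsites = 20) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", BASES, pwm$background), collapse = " "), "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            pwm$width, nsites)
  ), con)
  writeLines(apply(pwm$probs, 1L, function(r)
    paste(sprintf("%.6f", r), collapse = " ")), con)
  invisible(path)
}

#' Read the first motif from a MEME minimal format file
#'
#' @param path MEME motif file.
#' @return a `pwm` object (probabilities renormalised to sum to 1 per row).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  hdr <- grep("^letter-probability matrix", lines)
  if (!length(hdr)) stop("no letter-probability matrix in ", path)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr[1]]))
  rows <- lines[(hdr[1] + 1L):(hdr[1] + w)]
  probs <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  probs <- pmax(probs, 1e-9)
  probs <- probs / rowSums(probs)
  new_pwm(probs, bg)
}
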