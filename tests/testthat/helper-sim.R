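# Shared fixture builders. All fixtures are generated in code; tests that
# need randomness seed the RNG themselves.

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

sample_site_from <- function(pwm) {
  paste(apply(pwm$probs, 1L, function(p)
    sample(c("A", "C", "G", "T"), 1L, prob = p)), collapse = "")
}

# plant `site` into `seq` at 1-based position `at`
plant <- function(seq, site, at) {
  substr(seq, at, at + nchar(site) - 1L) <- site
  seq
}

# a small non-palindromic scanning model for strand-sensitive tests
asym_model <- function() {
  build_spaced_pwm(consensus_pwm("AAACAAGCCCGAACATGTAC", p = 0.9))
}

# file-path input list for run_pipeline from a written study directory
study_inputs <- function(dir, ct, mark_names) {
  list(
    genome = file.path(dir, ct, "genome.fa"),
    peaks = file.path(dir, ct, "peaks.narrowPeak"),
    peak_counts = file.path(dir, ct, "peak_counts.tsv"),
    genes = file.path(dir, ct, "genes.tsv"),
    marks = stats::setNames(
      file.path(dir, ct, "marks", paste0(mark_names, ".bed")), mark_names),
    counts = file.path(dir, ct, "counts.tsv"),
    meta = file.path(dir, ct, "samples.tsv")
  )
}

# exhaustive PWM score distribution for small widths: scores of all 4^w
# sequences plus their background probabilities (the brute-force oracle
# for the dynamic-programming p-value). With `granularity` set, sequences
# are scored under the same lattice convention the DP uses (per-column
# log-odds rounded to the nearest bin).
enumerate_scores <- function(pwm, granularity = NULL) {
  w <- pwm$width
  lo <- log2(pwm$probs / matrix(pwm$background, w, 4, byrow = TRUE))
  if (!is.null(granularity)) {
    # integer lattice units so ties are exact, scaled back at the end
    lo <- round(lo / granularity)
  }
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (k in seq_len(w)) {
    scores <- scores + lo[k, ][grid[, k]]
    probs <- probs * pwm$background[grid[, k]]
  }
  if (!is.null(granularity)) scores <- scores * granularity
  list(scores = scores, probs = probs)
}
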