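# De novo motif discovery by expectation-maximisation under the ZOOPS
# model (zero or one site per sequence, uniform position prior, i.i.d.
# background elsewhere), run on the summit-flanking sequences of the most
# enriched peaks. A deliberately transparent single-motif EM, not a full
# MEME replacement.

#' The n most enriched peaks
#'
#' @param peaks a `peak_set` with defined enrichment for every peak.
#' @param n how many to keep (default 1000); all peaks if fewer.
#' @return a `peak_set`, highest enrichment first (ties by name).
#' @export
top_peaks <- function(peaks, n = 1000L) {
  if (anyNA(peaks$enrichment)) {
    stop("all peaks must have defined enrichment; compute peak_enrichment ",
         "first and drop undefined peaks")
  }
  ord <- order(-peaks$enrichment, peaks$name)
  peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
}

#' Summit-flanking sequences of a peak set
#'
#' @param peaks a `peak_set`.
#' @param genome named character vector of chromosome sequences.
#' @param flank half-window around the summit in bp.
#' @return named character vector (names = peak names).
#' @export
peak_flank_seqs <- function(peaks, genome, flank = 300L) {
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    extract_window(genome[[chrom]], peaks$start[i] + peaks$summit_offset[i] + 1L,
                   flank)
  }, character(1))
  names(out) <- peaks$name
  out
}

# Precompute, per strand, the EM bookkeeping for a set of coded sequences:
# shifted code matrices are replaced by fixed linear-index lists so the
# M-step is pure subscript-and-sum.
zoops_prepare <- function(seqs, width) {
  n <- length(seqs)
  lens <- nchar(seqs)
  if (any(lens < width)) {
    stop("motif width exceeds the shortest sequence (",
         min(lens), " < ", width, ")")
  }
  Lmax <- max(lens)
  mmax <- Lmax - width + 1L
  pad <- function(codes) c(codes, rep(0L, Lmax - length(codes)))
  enc_f <- t(vapply(seqs, function(s) pad(encode_seq(s)), integer(Lmax)))
  enc_r <- t(vapply(seqs, function(s) pad(encode_seq(revcomp(s))),
                    integer(Lmax)))
  m_i <- lens - width + 1L
  mask <- outer(m_i, seq_len(mmax), ">=")
  idx <- function(enc) {
    lapply(seq_len(width), function(k) {
      sub <- enc[, k:(k + mmax - 1L), drop = FALSE]
      lapply(1:4, function(b) which(sub == b & mask))
    })
  }
  list(n = n, lens = lens, mmax = mmax, m_i = m_i, mask = mask,
       enc = list(`+` = enc_f, `-` = enc_r),
       idx = list(`+` = idx(enc_f), `-` = idx(enc_r)))
}

zoops_scores <- function(prep, lookup, strand) {
  enc <- prep$enc[[strand]]
  W <- ncol(lookup)
  S <- matrix(0, prep$n, prep$mmax)
  for (k in seq_len(W)) {
    sub <- enc[, k:(k + prep$mmax - 1L), drop = FALSE]
    S <- S + matrix(lookup[cbind(as.vector(sub) + 1L, k)],
                    prep$n, prep$mmax)
  }
  S
}

zoops_em_once <- function(prep, pwm0, background, lambda0, max_iter, tol,
                          bg_const) {
  probs <- pwm0
  lambda <- lambda0
  W <- nrow(probs)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    lookup <- rbind(0, t(log2(probs / matrix(background, W, 4,
                                             byrow = TRUE))))
    R <- lapply(c("+", "-"), function(st) {
      S <- zoops_scores(prep, lookup, st)
      r <- (lambda / (2 * prep$m_i)) * 2^S
      r[!prep$mask] <- 0
      r
    })
    names(R) <- c("+", "-")
    denom <- (1 - lambda) + rowSums(R[["+"]]) + rowSums(R[["-"]])
    ll <- sum(log(denom)) + bg_const
    if (ll < ll_prev - 1e-8 * max(1, abs(ll_prev))) {
      stop(sprintf("EM log-likelihood decreased (%.8f -> %.8f)",
                   ll_prev, ll))
    }
    ll_trace <- c(ll_trace, ll)
    post <- lapply(R, function(r) r / denom)
    z <- 1 - (1 - lambda) / denom
    # M-step
    lambda <- min(max(mean(z), 1e-6), 1 - 1e-6)
    counts <- matrix(0, W, 4)
    for (st in c("+", "-")) {
      p <- post[[st]]
      ix <- prep$idx[[st]]
      for (k in seq_len(W)) {
        for (b in 1:4) counts[k, b] <- counts[k, b] + sum(p[ix[[k]][[b]]])
      }
    }
    # pure ML update (a pseudocount here would break the monotone
    # likelihood guarantee); tiny floor only to keep log2 finite
    counts <- counts + 1e-9
    probs <- counts / rowSums(counts)
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }
  # per-sequence best site under the final posteriors
  best <- do.call(rbind, lapply(seq_len(prep$n), function(i) {
    pp <- post[["+"]][i, ]; pm <- post[["-"]][i, ]
    if (max(pp, pm) <= 0) {
      return(data.frame(seq = i, offset = NA_integer_,
                        strand = NA_character_, posterior = 0))
    }
    if (max(pp) >= max(pm)) {
      j <- which.max(pp)
      data.frame(seq = i, offset = j - 1L, strand = "+", posterior = pp[j])
    } else {
      j <- which.max(pm)
      data.frame(seq = i, offset = prep$lens[i] - (j - 1L) - nrow(probs),
                 strand = "-", posterior = pm[j])
    }
  }))
  list(probs = probs, lambda = lambda, loglik = ll_prev,
       ll_trace = ll_trace, converged = converged, sites = best)
}

#' ZOOPS-EM de novo motif discovery
#'
#' Fits a single motif of fixed width under the ZOOPS model (each sequence
#' carries zero or one site, on either strand, at a uniformly distributed
#' position; all other positions follow an i.i.d. background). EM restarts
#' are seeded deterministically from `seed`, each initialising the PWM
#' from a randomly chosen width-`width` subsequence smoothed with
#' pseudocount 0.5; the restart with the highest final log-likelihood
#' wins. The observed-data log-likelihood is asserted non-decreasing at
#' every iteration.
#'
#' @param seqs character vector of sequences over {A,C,G,T,N}, each at
#'   least `width` long.
#' @param width motif width (default 20).
#' @param n_restarts EM restarts (default 10).
#' @param max_iter maximum EM iterations per restart (default 200).
#' @param tol stop when the log-likelihood gain drops below this
#'   (default 1e-6).
#' @param seed integer seed controlling restart initialisation.
#' @param background base frequencies; estimated from `seqs` if NULL.
#' @param shift_polish after the best restart converges, retry EM from
#'   initialisations shifted by up to this many columns in either
#'   direction, keeping any phase with higher likelihood (corrects the
#'   off-by-one register optima EM is prone to); 0 disables.
#' @return list of class `discovery_result`: `pwm`, `site_posteriors`
#'   (data frame: seq, offset, strand, posterior), `lambda`,
#'   `information_content`, `loglik`, `ll_trace`, `n_restarts_used`,
#'   `converged`.
#' @export
discover_motif <- function(seqs, width = 20L, n_restarts = 10L,
                           max_iter = 200L, tol = 1e-6, seed = 1L,
                           background = NULL, shift_polish = 2L) {
  if (length(seqs) == 0L) stop("no input sequences")
  prep <- zoops_prepare(seqs, width)
  if (is.null(background)) background <- background_from_seqs(seqs)
  codes <- unlist(lapply(seqs, encode_seq))
  bg_const <- sum(log(background[codes[codes > 0L]]))
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    i <- sample.int(prep$n, 1L)
    j <- sample.int(prep$lens[i] - width + 1L, 1L)
    sub <- encode_seq(substr(seqs[i], j, j + width - 1L))
    counts <- matrix(0.5, width, 4)
    hit <- sub > 0L
    counts[cbind(which(hit), sub[hit])] <- counts[cbind(which(hit),
                                                        sub[hit])] + 1
    pwm0 <- counts / rowSums(counts)
    fit <- zoops_em_once(prep, pwm0, background, lambda0 = 0.5,
                         max_iter = max_iter, tol = tol, bg_const = bg_const)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # phase polishing: EM often settles one or two columns off register;
  # restarting from shifted versions of the winner finds the aligned phase
  if (shift_polish > 0L) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (k in c(-seq_len(shift_polish), seq_len(shift_polish))) {
        W <- nrow(best$probs)
        bgrow <- matrix(background, abs(k), 4, byrow = TRUE)
        init <- if (k > 0L) {
          rbind(best$probs[(k + 1L):W, , drop = FALSE], bgrow)
        } else {
          rbind(bgrow, best$probs[seq_len(W + k), , drop = FALSE])
        }
        init <- pmax(init, 1e-9)
        init <- init / rowSums(init)
        fit <- zoops_em_once(prep, init, background, lambda0 = best$lambda,
                             max_iter = max_iter, tol = tol,
                             bg_const = bg_const)
        if (fit$loglik > best$loglik + tol) {
          best <- fit
          improved <- TRUE
        }
      }
    }
  }
  pwm <- new_pwm(best$probs, background)
  structure(list(
    pwm = pwm,
    site_posteriors = best$sites,
    lambda = best$lambda,
    information_content = information_content(pwm),
    loglik = best$loglik,
    ll_trace = best$ll_trace,
    n_restarts_used = n_restarts,
    converged = best$converged
  ), class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf(
    "ZOOPS-EM motif: %s\nIC %.2f bits, site prior %.3f, loglik %.2f (%s)\n",
    pwm_consensus(x$pwm), x$information_content, x$lambda, x$loglik,
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}
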