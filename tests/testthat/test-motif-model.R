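near_one_pwm <- function(w) {
  # per-column probability ~1 on A; stands in for the textbook [1,0,0,0]
  # column that a strictly positive PWM cannot hold exactly
  probs <- matrix(1e-9, w, 4)
  probs[, 1] <- 1 - 3e-9
  new_pwm(probs)
}

test_that("log-odds scoring follows the per-column log2 ratio with N = 0", {
  pwm <- near_one_pwm(4)
  expect_equal(log_odds_score(pwm, "AAAA"), 4 * log2(4), tolerance = 1e-6)
  expect_equal(log_odds_score(pwm, "AANA"), 3 * log2(4), tolerance = 1e-6)

  flat <- new_pwm(matrix(0.25, 6, 4))
  expect_equal(log_odds_score(flat, "ACGTNA"), 0)

  expect_error(log_odds_score(pwm, "AAA"), "length")
  expect_error(log_odds_score(pwm, "AAXA"), "outside")
})

test_that("DP p-value is exact against exhaustive enumeration", {
  pwm <- near_one_pwm(4)
  maxs <- log_odds_score(pwm, "AAAA")
  expect_equal(score_pvalue(pwm, maxs), 1 / 256, tolerance = 1e-9)
  expect_equal(score_pvalue(pwm, -1e6), 1)

  set.seed(101)
  g <- 1e-4
  for (w in c(4L, 6L, 8L)) {
    probs <- matrix(stats::rgamma(4 * w, 1) + 0.05, w, 4)
    pwm <- new_pwm(probs / rowSums(probs))
    # oracle under the method's own scoring convention (lattice-rounded
    # columns): the DP tail must match exhaustive enumeration exactly
    lat <- enumerate_scores(pwm, granularity = g)
    ord <- order(lat$scores, decreasing = TRUE)
    cs <- cumsum(lat$probs[ord])
    keep <- !duplicated(lat$scores[ord], fromLast = TRUE)
    qs <- lat$scores[ord][keep]
    dp <- score_pvalue(pwm, qs, granularity = g)
    expect_lt(max(abs(dp - cs[keep])), 1e-9)

    # float queries are bracketed by exact float tails at +- width * g
    fl <- enumerate_scores(pwm)
    qf <- sort(sample(unique(fl$scores), 50))
    dpf <- score_pvalue(pwm, qf, granularity = g)
    lo <- vapply(qf, function(q) sum(fl$probs[fl$scores >= q + w * g]), 0)
    hi <- vapply(qf, function(q) sum(fl$probs[fl$scores >= q - w * g]), 0)
    expect_true(all(dpf >= lo - 1e-12 & dpf <= hi + 1e-12))
  }
})

test_that("p-value is non-increasing in score and in (0, 1]", {
  pwm <- pwm_p53()
  grid <- seq(-40, 30, by = 0.25)
  p <- score_pvalue(pwm, grid)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p > 0 & p <= 1))
})

test_that("spacer variants are built from the two half sites", {
  full <- pwm_p53()
  model <- build_spaced_pwm(full)
  expect_equal(vapply(model$variants, function(v) v$width, 0L),
               stats::setNames(20L + 0:15, as.character(0:15)))
  expect_equal(model$variants[["0"]]$probs, full$probs,
               ignore_attr = TRUE)
  v15 <- model$variants[["15"]]
  for (i in 11:25) {
    expect_equal(unname(v15$probs[i, ]), full$background)
  }
  expect_equal(v15$probs[1:10, ], model$half1$probs, ignore_attr = TRUE)
  expect_error(build_spaced_pwm(model$half1), "width 20")
})

test_that("scan_window finds planted sites and applies the tie rules", {
  model <- asym_model()
  cons <- pwm_consensus(model$variants[["0"]])
  set.seed(17)
  win <- plant(random_seq(600), cons, 138)  # 0-based offset 137
  hit <- scan_window(win, model)
  expect_equal(hit$offset, 137L)
  expect_equal(hit$spacer, 0L)
  expect_equal(hit$matched_seq, cons)
  expect_lt(hit$pvalue, 1e-4)

  # spaced site on the minus strand
  sp <- paste0(substr(cons, 1, 10), random_seq(7), substr(cons, 11, 20))
  win2 <- plant(random_seq(600),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(sp))), 301)
  hit2 <- scan_window(win2, model)
  expect_equal(hit2$spacer, 7L)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$offset, 300L)
  expect_equal(hit2$matched_seq, sp)

  # reverse-complement invariance: strand flips, p-value identical
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(win2)))
  hit2rc <- scan_window(rc2, model)
  expect_equal(hit2rc$strand, "+")
  expect_equal(hit2rc$pvalue, hit2$pvalue)
  expect_equal(hit2rc$spacer, hit2$spacer)

  # two identical sites: smaller offset wins
  win3 <- plant(plant(random_seq(600), cons, 101), cons, 401)
  expect_equal(scan_window(win3, model)$offset, 100L)

  expect_null(scan_window(strrep("N", 600), model))
  expect_error(scan_window(plant(random_seq(600), "Z", 5), model),
               "outside")

  all_hits <- scan_window(win3, model, report_all = TRUE)
  expect_gte(nrow(all_hits), 2L)
  expect_true(!is.unsorted(all_hits$pvalue))
})

test_that("hit classification and spacer distribution count correctly", {
  hits <- data.frame(peak_name = c("a", "b", "c"),
                     spacer = c(0L, 0L, 3L))
  cl <- classify_hits(hits)
  expect_equal(unname(cl$frequencies),
               c(0, 2 / 3, 1 / 3))
  expect_equal(sum(cl$frequencies), 1)

  none <- data.frame(peak_name = c("a", "b"), spacer = c(NA, NA))
  expect_equal(unname(classify_hits(none)$frequencies), c(1, 0, 0))

  hits2 <- data.frame(peak_name = letters[1:4], spacer = c(2L, 2L, 5L, 0L))
  d <- spacer_distribution(hits2)
  expect_equal(unname(d[c("2", "5")]), c(2L, 1L))
  expect_equal(sum(d), 3L)  # unsplit hit not counted
  expect_equal(sum(spacer_distribution(none)), 0L)
})

test_that("group_compare reproduces the pooled two-sample t", {
  same <- list(g1 = c(1, 2, 3), g2 = c(1, 2, 3))
  gc <- group_compare(same)
  expect_equal(gc$tests$t, 0)
  expect_equal(gc$tests$pvalue, 1)

  gc2 <- group_compare(list(lo = c(1, 2, 3), hi = c(4, 5, 6)))
  expect_equal(gc2$tests$t, -3.674235, tolerance = 1e-5)
  expect_equal(gc2$tests$df, 4)
  expect_equal(gc2$tests$pvalue, 0.02131164, tolerance = 1e-5)
  expect_equal(gc2$summaries$median, c(2, 5))

  expect_error(group_compare(list(a = 1, b = c(1, 2))), ">= 2")
})

test_that("MEME minimal format round-trips a PWM", {
  pwm <- pwm_p53(background = c(0.3, 0.2, 0.2, 0.3))
  f <- tempfile(fileext = ".meme")
  write_meme(pwm, f, name = "p53_RE")
  back <- read_meme(f)
  expect_equal(back$probs, pwm$probs, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(back$background, pwm$background, tolerance = 1e-5)
})
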