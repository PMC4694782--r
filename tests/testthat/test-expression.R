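test_that("rpkm follows the exon-mapped formula and is linear in counts", {
  counts <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  r <- rpkm(counts, exon_lengths = c(1000, 500), totals = 1e6)
  expect_equal(unname(r[, 1]), c(10, 0))
  expect_error(rpkm(counts, c(0, 500), totals = 1e6), "lengths")
  expect_error(rpkm(counts, c(1000, 500), totals = 0), "totals")

  set.seed(9)
  cm <- matrix(rpois(60, 50), 10, 6)
  rownames(cm) <- paste0("g", 1:10)
  len <- sample(500:5000, 10)
  tot <- sample(1e6:2e6, 6)
  r1 <- rpkm(cm, len, tot)
  expect_equal(rpkm(3 * cm, len, tot), 3 * r1)
  expect_equal(rpkm(cm, 2 * len, tot), r1 / 2)
  expect_equal(rpkm(cm, len, 2 * tot), r1 / 2)
})

test_that("nb_de_test: null fold changes, q monotonicity, effect recovery", {
  counts <- matrix(rep(c(40L, 90L), each = 8), 2, 8, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     treatment = rep(c("mock", "IR"), each = 4))
  de <- nb_de_test(counts, meta)
  expect_equal(de$log2fc, c(0, 0))

  expect_error(
    nb_de_test(counts[, c(1, 5:8)],
               meta[c(1, 5:8), , drop = FALSE]), "2 replicates")

  set.seed(33)
  n <- 1100
  mu <- rlnorm(n, log(100), 0.8)
  fold <- rep(c(1, 4), c(1000, 100))
  cm <- sapply(1:8, function(j) {
    f <- if (j > 4) fold else 1
    rnbinom(n, mu = mu * f, size = 1 / 0.05)
  })
  rownames(cm) <- sprintf("g%04d", 1:n)
  de <- nb_de_test(cm, meta)
  # median-of-ratios normalisation absorbs a little of the planted shift,
  # hence the absolute 0.2 allowance around log2(4)
  expect_lt(abs(median(de$log2fc[fold == 4]) - 2), 0.2)
  # BH q-values are monotone in p after the step-up transform
  ord <- order(de$pvalue)
  expect_true(!is.unsorted(de$qvalue[ord]))
  expect_true(all(de$qvalue >= 0 & de$qvalue <= 1, na.rm = TRUE))
})

test_that("DEG calling uses strict thresholds and the expression floor", {
  de <- data.frame(
    gene_id = c("up", "edge_lfc", "edge_q", "down", "low_rpkm"),
    log2fc = c(0.60, 0.58, 0.80, -0.90, 1.5),
    qvalue = c(0.04, 0.04, 0.05, 0.01, 0.001)
  )
  rp <- matrix(c(2, 2, 2, 3, 0.9), 5, 2,
               dimnames = list(de$gene_id, c("a", "b")))
  degs <- call_degs(de, rp)
  expect_equal(degs$up, "up")        # 0.58 exactly and q = 0.05 excluded
  expect_equal(degs$down, "down")
  expect_length(intersect(degs$up, degs$down), 0)
})

test_that("the 1.5x dependence rule on the linear fold scale", {
  expect_equal(classify_dependence(log2(4), log2(2), "up"), "DEP")
  expect_equal(classify_dependence(log2(1.6), log2(1.5), "up"), "INDEP")
  expect_equal(classify_dependence(log2(0.25), log2(0.5), "down"), "DEP")
  expect_equal(classify_dependence(log2(1.5), NA, "up"), "DEP")  # ko -> 0
  # inclusive at exactly 1.5
  expect_equal(classify_dependence(log2(3), log2(2), "up"), "DEP")
  expect_error(classify_dependence(1, 0, "sideways"), "direction")
})

test_that("regulatory modes combine DEG calls with dependence", {
  de_wt <- data.frame(gene_id = c("a", "b", "c"),
                      log2fc = c(2, -2, 0.1))
  de_ko <- data.frame(gene_id = c("a", "b", "c"),
                      log2fc = c(0, -2, 0))
  degs <- list(up = "a", down = "b")
  m <- regulatory_modes(de_wt, de_ko, degs)
  expect_equal(m$mode, c("UP_DEP", "DOWN_INDEP", "UNCHANGED"))
})

test_that("Spearman clustering merges duplicates first and names bad samples", {
  set.seed(12)
  m <- matrix(rlnorm(400, log(10), 1), 100, 4,
              dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  m[, 2] <- m[, 1]
  hc <- spearman_cluster(m)
  expect_lt(hc$height[1], 1e-12)
  expect_true(all(hc$merge[1, ] < 0))
  expect_setequal(hc$labels[-hc$merge[1, ]], c("s1", "s2"))

  two <- cbind(a = 1:20, b = 20:1) * 1.0
  hc2 <- spearman_cluster(two, min_rpkm = 0)
  expect_equal(hc2$height, 2)  # rho = -1

  bad <- cbind(x = rlnorm(50, log(10)), flatline = rep(5, 50))
  expect_error(spearman_cluster(bad, min_rpkm = 0), "flatline")

  # planted two-group structure (independent rank profiles per group;
  # a monotone transform would be invisible to Spearman)
  set.seed(4)
  base_a <- rlnorm(300, log(20), 1)
  base_b <- rlnorm(300, log(20), 1)
  noisy <- function(v) v * exp(rnorm(300, 0, 0.05))
  grp <- cbind(a1 = noisy(base_a), a2 = noisy(base_a),
               b1 = noisy(base_b), b2 = noisy(base_b))
  hc3 <- spearman_cluster(grp)
  groups <- split(names(stats::cutree(hc3, 2)), stats::cutree(hc3, 2))
  expect_setequal(vapply(groups, paste, "", collapse = "+"),
                  c("a1+a2", "b1+b2"))
})

test_that("gene-set enrichment filters sizes and matches the closed form", {
  universe <- paste0("g", 1:20)
  genes <- paste0("g", 1:10)
  sets <- list(full = paste0("g", 1:10 + 10),   # disjoint from the query
               tiny = paste0("g", 1:5),
               hit = paste0("g", 1:10))
  res <- geneset_enrichment(genes, universe, sets,
                            min_size = 9, max_size = 2000)
  expect_false("tiny" %in% res$set)            # size 5 filtered out
  expect_equal(res$pvalue[res$set == "full"], 1)
  expect_equal(res$pvalue[res$set == "hit"], 1 / choose(20, 10),
               tolerance = 1e-9)
  expect_error(geneset_enrichment(c("g1", "zz"), universe, sets), "subset")

  # the study's bounds: a 10-gene set is excluded ("more than 10"),
  # an 11-gene set is kept
  sets2 <- list(ten = paste0("g", 1:10), eleven = paste0("g", 1:11))
  res2 <- geneset_enrichment(genes, universe, sets2)
  expect_equal(res2$set, "eleven")
})

test_that("GMT parsing returns named gene vectors", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg9"), f)
  g <- read_gmt(f)
  expect_equal(g$setA, c("g1", "g2", "g3"))
  expect_equal(g$setB, "g9")
})

test_that("imported DE tables are validated", {
  f <- tempfile()
  write_tsv <- function(df) utils::write.table(
    df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(data.frame(gene_id = "g", log2fc = 1, qvalue = 0.01))
  expect_equal(import_de(f)$gene_id, "g")
  write_tsv(data.frame(gene = "g", fc = 1))
  expect_error(import_de(f), "columns")
})
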