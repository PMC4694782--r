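make_link_fixture <- function() {
  peaks <- peak_set("chr1", c(1000L, 3000L, 50000L),
                    c(1400L, 3400L, 50400L),
                    name = c("pkA", "pkB", "pkFar"),
                    enrichment = c(5, 3, 4))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(2000L, 20000L), strand = c("+", "+"))
  windows <- promoter_windows(genes, c(chr1 = 1e6))
  hits <- data.frame(
    peak_name = c("pkA", "pkB", "pkFar"),
    offset = c(1L, 2L, 3L), strand = "+",
    spacer = c(3L, 0L, NA), score = c(10, 20, NA),
    pvalue = c(1e-5, 1e-8, NA), matched_seq = NA_character_
  )
  list(peaks = peaks, genes = genes, windows = windows, hits = hits)
}

test_that("genes link to the best promoter peak by motif p-value", {
  f <- make_link_fixture()
  links <- link_genes_to_peaks(f$genes, f$peaks, f$windows, f$hits)
  # g1's window covers both pkA (p 1e-5, spacer 3) and pkB (p 1e-8,
  # unsplit): the lower p-value wins
  expect_equal(links$peak_name[links$gene_id == "g1"], "pkB")
  expect_equal(links$motif_class[links$gene_id == "g1"], "UNSPLIT")
  # g2 has no overlapping peak
  expect_true(is.na(links$peak_name[links$gene_id == "g2"]))
  expect_equal(links$motif_class[links$gene_id == "g2"], "NO_MOTIF")

  # motif-free peaks rank by enrichment, then name
  hits_none <- f$hits
  hits_none$pvalue <- NA
  hits_none$spacer <- NA
  links2 <- link_genes_to_peaks(f$genes, f$peaks, f$windows, hits_none)
  expect_equal(links2$peak_name[links2$gene_id == "g1"], "pkA")  # enr 5 > 3
  expect_equal(links2$motif_class[links2$gene_id == "g1"], "NO_MOTIF")
})

test_that("the mode x motif cross-tab partitions bound genes", {
  links <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    peak_name = c("p1", "p2", NA, "p4"),
    motif_class = c("UNSPLIT", "SPACED", "NO_MOTIF", "UNSPLIT"),
    motif_pvalue = c(1e-8, 1e-5, NA, 1e-6), spacer = c(0L, 4L, NA, 0L)
  )
  modes <- data.frame(gene_id = paste0("g", 1:4),
                      mode = c("UP_DEP", "UP_INDEP", "UNCHANGED",
                               "UP_DEP"))
  xt <- regulatory_crosstab(links, modes)
  expect_equal(sum(xt$counts), 3L)        # only the bound genes
  expect_equal(xt$counts["UP_DEP", "UNSPLIT"], 2L)
  expect_equal(xt$percent["UP_DEP", "UNSPLIT"], 100)
  expect_equal(unname(rowSums(xt$percent, na.rm = TRUE)[c("UP_DEP",
                                                          "UP_INDEP")]),
               c(100, 100))
  expect_equal(xt$n_bound + 1L, xt$n_genes)

  empty <- regulatory_crosstab(
    data.frame(gene_id = "g", peak_name = NA_character_,
               motif_class = "NO_MOTIF", motif_pvalue = NA,
               spacer = NA_integer_),
    data.frame(gene_id = "g", mode = "UNCHANGED"))
  expect_equal(sum(empty$counts), 0L)
})

test_that("fold-change group summaries exclude singletons from testing", {
  modes <- data.frame(
    gene_id = sprintf("g%02d", 1:9),
    mode = c(rep("UP_DEP", 4), rep("UP_INDEP", 4), "DOWN_DEP"),
    wt_log2fc = c(2, 2, 2, 2, 1, 1, 1, 1, -3)
  )
  links <- data.frame(gene_id = modes$gene_id, peak_name = "p",
                      motif_class = "UNSPLIT", motif_pvalue = 1e-6,
                      spacer = 0L)
  out <- fc_by_category(modes, links)
  expect_equal(out$excluded$group, "DOWN_DEP.UNSPLIT")
  tst <- out$tests[out$tests$group1 == "UP_DEP.UNSPLIT" |
                     out$tests$group2 == "UP_DEP.UNSPLIT", ]
  expect_equal(nrow(tst), 1L)
  # identical within-group values, different between: p from pooled t
  expect_lt(tst$pvalue, 1e-6)

  same <- fc_by_category(
    data.frame(gene_id = c("a", "b", "c", "d"),
               mode = rep(c("UP_DEP", "UP_INDEP"), each = 2),
               wt_log2fc = c(1, 2, 1, 2)),
    data.frame(gene_id = c("a", "b", "c", "d"), peak_name = "p",
               motif_class = "NO_MOTIF", motif_pvalue = NA,
               spacer = NA_integer_))
  expect_equal(same$tests$pvalue, 1)
})

test_that("core response is exact set intersection with coverage", {
  a <- sprintf("g%03d", 1:70)          # 50 shared + 20 private
  b <- sprintf("g%03d", c(1:50, 101:130))
  cr <- core_response(a, b)
  expect_equal(cr$core, sprintf("g%03d", 1:50))
  expect_equal(cr$fraction_a, 50 / 70)
  expect_equal(cr$fraction_b, 50 / 80)

  self <- core_response(a, a)
  expect_equal(self$core, sort(a))
  expect_equal(c(self$fraction_a, self$fraction_b), c(1, 1))

  disj <- core_response(c("x"), c("y"))
  expect_length(disj$core, 0)
  expect_equal(c(disj$fraction_a, disj$fraction_b), c(0, 0))
})

test_that("core candidates are dependent, bound and unsplit", {
  modes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      mode = c("UP_DEP", "UP_DEP", "UP_INDEP", "UP_DEP"),
                      wt_log2fc = 1, ko_log2fc = 0)
  links <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    peak_name = c("p1", NA, "p3", "p4"),
    motif_class = c("UNSPLIT", "NO_MOTIF", "UNSPLIT", "SPACED"),
    motif_pvalue = NA, spacer = NA_integer_
  )
  expect_equal(core_candidates(modes, links), "g1")
})
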