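test_that("generators are pure functions of the configuration", {
  cfg <- sim_config(seed = 14, n_peaks = 60L, n_genes = 150L)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$registry, g2$registry)
  c1 <- simulate_counts(cfg, simulate_annotation(cfg, g1)$genes)
  c2 <- simulate_counts(cfg, simulate_annotation(cfg, g2)$genes)
  expect_identical(c1$counts, c2$counts)

  d1 <- tempfile(); d2 <- tempfile()
  simulate_study(cfg, dir = d1)
  simulate_study(cfg, dir = d2)
  for (f in c("B/genome.fa", "B/peaks.narrowPeak", "B/counts.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("planted sites exist verbatim in the emitted genome", {
  cfg <- sim_config(seed = 2, n_peaks = 80L)
  g <- simulate_genome(cfg)
  reg <- g$registry[g$registry$motif_class != "NO_MOTIF", ]
  expect_gt(nrow(reg), 0L)
  for (i in seq_len(nrow(reg))) {
    w <- nchar(reg$site_seq[i])
    got <- substr(g$genome[[reg$chrom[i]]], reg$site_start[i] + 1L,
                  reg$site_start[i] + w)
    want <- if (reg$site_strand[i] == "+") reg$site_seq[i] else
      revcomp(reg$site_seq[i])
    expect_identical(got, want)
  }
  # spacers only on SPACED sites, in 1..15
  expect_true(all(reg$spacer[reg$motif_class == "SPACED"] %in% 1:15))
  expect_true(all(reg$spacer[reg$motif_class == "UNSPLIT"] == 0L))
})

test_that("zero motif rates plant nothing; planted fractions track config", {
  none <- c(unsplit = 0, spaced = 0, none = 1)
  cfg0 <- sim_config(seed = 3, n_peaks = 40L,
                     motif_rates = list(promoter = none, enhancer = none,
                                        unmarked = none))
  g0 <- simulate_genome(cfg0)
  expect_true(all(g0$registry$motif_class == "NO_MOTIF"))

  cfg <- sim_config(seed = 8, n_peaks = 600L)
  g <- simulate_genome(cfg)
  frac <- prop.table(table(g$registry$chromatin_class))
  # binomial 99.9% CI half-width at n=600 is ~0.066
  expect_equal(unname(frac["promoter"]), 0.40, tolerance = 0.2)
  expect_equal(unname(frac["enhancer"]), 0.30, tolerance = 0.25)
})

test_that("peak counts produce the planted enrichment ordering", {
  cfg <- sim_config(seed = 5, n_peaks = 300L)
  sim <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, sim)
  expect_equal(nrow(pk$peaks), 300L)
  expect_true(all(pk$peaks$start + pk$peaks$summit_offset ==
                    pk$truth$summit))
  peaks <- peak_enrichment(pk$peaks)
  m <- tapply(peaks$enrichment, pk$truth$motif_class, mean, na.rm = TRUE)
  expect_gt(m[["UNSPLIT"]], m[["SPACED"]])
  expect_gt(m[["SPACED"]], m[["NO_MOTIF"]])

  # equal-means negative control: classes statistically indistinguishable
  cfg_eq <- sim_config(seed = 5, n_peaks = 300L,
                       chip_rpm = c(UNSPLIT = 30, SPACED = 30,
                                    NO_MOTIF = 30))
  pk_eq <- simulate_peaks(cfg_eq, simulate_genome(cfg_eq))
  peaks_eq <- peak_enrichment(pk_eq$peaks)
  gc <- group_compare(split(peaks_eq$enrichment, pk_eq$truth$motif_class))
  expect_true(all(gc$tests$pvalue > 0.01))

  empty_cfg <- sim_config(seed = 1, n_peaks = 0L)
  expect_equal(nrow(simulate_peaks(empty_cfg,
                                   simulate_genome(empty_cfg))$peaks), 0L)
})

test_that("annotation construction is disjoint and recovered exactly", {
  cfg <- sim_config(seed = 6, n_peaks = 200L, n_genes = 400L)
  sim <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, sim)
  ann <- simulate_annotation(cfg, sim)
  windows <- promoter_windows(ann$genes, ann$chrom_lens)
  cl <- classify_peaks(peak_enrichment(pk$peaks), windows, ann$marks)
  planted <- c(promoter = "PROMOTER", enhancer = "ENHANCER",
               unmarked = "UNMARKED_DISTAL")[sim$registry$chromatin_class]
  expect_equal(cl$classes$class, unname(planted))
  expect_equal(sum(cl$counts), 200L)

  # all-unmarked config leaves every mark set empty
  cfg_u <- sim_config(seed = 6, n_peaks = 30L, n_genes = 60L,
                      class_fractions = c(promoter = 0, enhancer = 0,
                                          unmarked = 1))
  ann_u <- simulate_annotation(cfg_u, simulate_genome(cfg_u))
  expect_true(all(vapply(ann_u$marks, nrow, 0L) == 0L))
})

test_that("count simulation hits its base means in the Poisson limit", {
  cfg <- sim_config(seed = 7, n_peaks = 20L, n_genes = 60L,
                    dispersion = 0, n_replicates = 50L,
                    fraction_null = 1)
  ann <- simulate_annotation(cfg, simulate_genome(cfg))
  cnt <- simulate_counts(cfg, ann$genes)
  mock_wt <- cnt$meta$genotype == "WT" & cnt$meta$treatment == "mock"
  mns <- rowMeans(cnt$counts[, mock_wt])
  rel <- abs(mns - cnt$truth$base_mean) /
    pmax(cnt$truth$base_mean, 1)
  # Poisson se of the mean at n = 50 is sqrt(mu/50); allow 5 sigma
  expect_true(all(rel < 5 / sqrt(50 * pmax(cnt$truth$base_mean, 1)) + 0.05))
  expect_true(all(cnt$truth$wt_fold == 1))
})

test_that("planted mode fractions and the study design are honoured", {
  cfg <- sim_config(seed = 9, n_peaks = 120L, n_genes = 800L,
                    fraction_null = 0.6)
  ann <- simulate_annotation(cfg, simulate_genome(cfg))
  cnt <- simulate_counts(cfg, ann$genes)
  tab <- table(cnt$truth$mode)
  expect_equal(unname(tab["UP_DEP"]), 80L)   # 800 * 0.4 / 4
  expect_equal(unname(tab["DOWN_INDEP"]), 80L)
  expect_equal(sum(tab), 800L)

  study <- simulate_study(sim_config(seed = 10, n_peaks = 260L,
                                     n_genes = 600L),
                          cell_types = c("B", "nonB"),
                          n_core = 12L, n_private = c(5L, 6L))
  core <- study$core_genes
  expect_length(core, 12L)
  for (ct in c("B", "nonB")) {
    s <- study[[ct]]
    md <- s$modes$mode[match(core, s$modes$gene_id)]
    expect_true(all(md == "UP_DEP"))
    bound <- s$genes[match(core, s$genes$gene_id), ]
    expect_true(all(!is.na(bound$bound_peak)))
    expect_true(all(bound$motif_class == "UNSPLIT"))
  }
  # private genes are dependent only in their own cell type
  privA <- setdiff(
    study$B$modes$gene_id[study$B$modes$mode == "UP_DEP" &
                            study$B$modes$gene_id %in%
                            study$B$genes$gene_id[
                              study$B$genes$motif_class == "UNSPLIT" &
                                !is.na(study$B$genes$bound_peak)]],
    core)
  mdB <- study$nonB$modes$mode[match(privA, study$nonB$modes$gene_id)]
  gB <- study$nonB$genes[match(privA, study$nonB$genes$gene_id), ]
  expect_true(all(mdB != "UP_DEP" | is.na(gB$bound_peak) |
                    gB$motif_class != "UNSPLIT"))
})

test_that("YAML round-trip reproduces a configuration", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 4L, n_peaks = 33L, gc_content = 0.5,
                        dispersion = 0.2), f)
  cfg <- sim_config_from_yaml(f)
  expect_equal(cfg$n_peaks, 33L)
  expect_equal(cfg$dispersion, 0.2)
  expect_equal(cfg$genome_length, 33L * cfg$bp_per_peak)
})
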