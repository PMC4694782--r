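# Synthetic-data generators. Every generator is a pure function of the
# configuration: it seeds the RNG itself (from cfg$seed plus a fixed
# per-stage offset), so reruns are byte-identical and stages can be called
# in any order. The generators emulate the data structure behind the real
# study: a toy genome with planted response elements, peak calls whose
# signal tracks the motif class, promoter/enhancer/unmarked chromatin
# structure, and WT/KO x mock/IR negative-binomial count matrices with
# planted regulatory modes.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators with defaults
#' that mirror the study conditions: ~500 binding sites whose signal
#' ranks unsplit > spaced > no-motif, a -5/+2 kb promoter structure with
#' active-mark rates, and a 2 x 2 (genotype x irradiation) expression
#' design with four planted regulatory modes.
#'
#' @param seed integer master seed; each generator stage derives its own
#'   stream from it.
#' @param n_peaks number of binding sites.
#' @param bp_per_peak genome bp allocated per site (controls locus
#'   spacing; must keep promoter windows of neighbouring loci disjoint).
#' @param gc_content background GC fraction.
#' @param class_fractions named fractions (promoter, enhancer, unmarked)
#'   summing to 1.
#' @param motif_rates per chromatin class, fractions (unsplit, spaced,
#'   none) summing to 1.
#' @param spacer_weights sampling weights for spacer lengths 1..15.
#' @param chip_rpm mean ChIP reads-per-million per motif class.
#' @param input_rpm mean input reads-per-million.
#' @param rpm_sdlog lognormal noise (sd of log) on the per-peak ChIP rpm.
#' @param chip_libsize,input_libsize library sizes.
#' @param peak_width_range min/max called peak width in bp.
#' @param mark_rates per chromatin class, named Bernoulli rates for
#'   H3K4me3, H3K4me1, H3K27ac, RNApolII, DHS.
#' @param mark_halfwidth half-width of simulated mark peaks in bp.
#' @param consensus_only plant the consensus sequence instead of sampling
#'   sites from the PWM.
#' @param n_genes total genes in the expression layer.
#' @param exon_meanlog,exon_sdlog lognormal exonic length model.
#' @param base_meanlog,base_sdlog lognormal baseline-mean model.
#' @param dispersion NB dispersion (var = mu + dispersion * mu^2).
#' @param n_replicates,ko_replicates replicates per condition for WT / KO.
#' @param fraction_null fraction of genes with no IR response.
#' @param effects per planted mode, IR fold changes c(wt=, ko=).
#' @param updep_bound_unsplit fraction of UP_DEP genes drawn from the pool
#'   of genes bound via an unsplit-motif promoter peak (pool permitting).
#' @param force_promoter_unsplit guarantee at least this many loci are
#'   promoter-class with an unsplit site (a random subset is reserved
#'   before the multinomial class draw); used by [simulate_study()] to
#'   host its planted core.
#' @param flank scanning half-window, used to size peak loci.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_peaks = 500L,
    bp_per_peak = 16000L,
    gc_content = 0.42,
    class_fractions = c(promoter = 0.40, enhancer = 0.30, unmarked = 0.30),
    motif_rates = list(
      promoter = c(unsplit = 0.35, spaced = 0.20, none = 0.45),
      enhancer = c(unsplit = 0.25, spaced = 0.20, none = 0.55),
      unmarked = c(unsplit = 0.20, spaced = 0.15, none = 0.65)
    ),
    spacer_weights = rep(1, 15),
    chip_rpm = c(UNSPLIT = 60, SPACED = 35, NO_MOTIF = 15),
    input_rpm = 5,
    rpm_sdlog = 0.25,
    chip_libsize = 1e7,
    input_libsize = 1e7,
    peak_width_range = c(300L, 600L),
    mark_rates = list(
      promoter = c(H3K4me3 = 0.9, H3K4me1 = 0.5, H3K27ac = 0.7,
                   RNApolII = 0.85, DHS = 0.9),
      enhancer = c(H3K4me3 = 0, H3K4me1 = 1, H3K27ac = 0.6,
                   RNApolII = 0, DHS = 0.7),
      unmarked = c(H3K4me3 = 0, H3K4me1 = 0, H3K27ac = 0,
                   RNApolII = 0, DHS = 0)
    ),
    mark_halfwidth = 500L,
    consensus_only = FALSE,
    n_genes = 2000L,
    exon_meanlog = log(2000), exon_sdlog = 0.6,
    base_meanlog = log(100), base_sdlog = 1,
    dispersion = 0.05,
    n_replicates = 4L,
    ko_replicates = n_replicates,
    fraction_null = 0.7,
    effects = list(UP_DEP = c(wt = 4, ko = 1),
                   UP_INDEP = c(wt = 3, ko = 3),
                   DOWN_DEP = c(wt = 0.25, ko = 1),
                   DOWN_INDEP = c(wt = 1 / 3, ko = 1 / 3)),
    updep_bound_unsplit = 0.6,
    force_promoter_unsplit = 0L,
    flank = 300L) {
  cfg <- as.list(environment())
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1")
  }
  for (k in names(motif_rates)) {
    if (abs(sum(motif_rates[[k]]) - 1) > 1e-9) {
      stop("motif_rates$", k, " must sum to 1")
    }
  }
  if (any(unlist(lapply(effects, function(e) e <= 0)))) {
    stop("effect folds must be > 0")
  }
  cfg$genome_length <- as.integer(n_peaks) * as.integer(bp_per_peak)
  if (cfg$genome_length < 10 * n_peaks * 2 * flank) {
    stop("bp_per_peak too small for the scanning window")
  }
  structure(cfg, class = "sim_config")
}

#' Load a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @export
sim_config_from_yaml <- function(path) {
  args <- yaml::read_yaml(path)
  for (nm in c("class_fractions", "chip_rpm")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  for (nm in c("motif_rates", "mark_rates", "effects")) {
    if (!is.null(args[[nm]])) args[[nm]] <- lapply(args[[nm]], unlist)
  }
  do.call(sim_config, args)
}

stage_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) + offset) %% (.Machine$integer.max - 1))
}

sample_site <- function(pwm, consensus_only) {
  if (consensus_only) return(pwm_consensus(pwm))
  paste(apply(pwm$probs, 1L, function(p) sample(BASES, 1L, prob = p)),
        collapse = "")
}

#' Simulate a toy genome with planted response elements
#'
#' Generates i.i.d. background sequence at the configured GC content,
#' places non-overlapping peak loci on a regular grid (one locus per
#' `bp_per_peak`), assigns each locus a chromatin class and a motif class,
#' and writes a sampled (or consensus) dimeric site centred on the summit
#' -- adjacent half sites for UNSPLIT, a background spacer of 1-15 nt for
#' SPACED, nothing for NO_MOTIF.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named character vector), `chrom_lens`,
#'   `registry` (data frame: one row per planted locus with its truth
#'   labels) and `cfg`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(stage_seed(cfg, 0))
  n <- cfg$n_peaks
  block <- cfg$bp_per_peak
  n_chrom <- max(1L, ceiling(n / 250L))
  per_chrom <- diff(floor(seq(0, n, length.out = n_chrom + 1L)))
  gc <- cfg$gc_content
  base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  pwm <- pwm_p53()
  genome <- character(n_chrom)
  names(genome) <- paste0("chr", seq_len(n_chrom))
  # class labels drawn up front; a random subset can be reserved as
  # promoter+unsplit to host planted designs
  cls_all <- sample(names(cfg$class_fractions), n, replace = TRUE,
                    prob = cfg$class_fractions)
  mcls_all <- vapply(cls_all, function(cl) {
    c("UNSPLIT", "SPACED", "NO_MOTIF")[
      sample.int(3L, 1L, prob = cfg$motif_rates[[cl]])]
  }, character(1))
  if (cfg$force_promoter_unsplit > 0L) {
    if (cfg$force_promoter_unsplit > n) {
      stop("force_promoter_unsplit exceeds n_peaks")
    }
    reserve <- sample.int(n, cfg$force_promoter_unsplit)
    cls_all[reserve] <- "promoter"
    mcls_all[reserve] <- "UNSPLIT"
  }
  reg <- list()
  peak_i <- 0L
  for (ci in seq_len(n_chrom)) {
    npk <- per_chrom[ci]
    clen <- npk * block
    seq_c <- paste(sample(BASES, clen, replace = TRUE, prob = base_probs),
                   collapse = "")
    if (npk > 0L) for (k in seq_len(npk)) {
      peak_i <- peak_i + 1L
      center <- (k - 1L) * block + block %/% 2L
      summit <- center + sample(-1000:1000, 1L)  # 0-based
      cls <- cls_all[peak_i]
      mcls <- mcls_all[peak_i]
      spacer <- NA_integer_
      site_start <- NA_integer_
      site_strand <- NA_character_
      site_seq <- NA_character_
      if (mcls != "NO_MOTIF") {
        spacer <- if (mcls == "UNSPLIT") 0L else
          sample.int(15L, 1L, prob = cfg$spacer_weights)
        halves <- sample_site(pwm, cfg$consensus_only)
        site_seq <- if (spacer > 0L) {
          paste0(substr(halves, 1, 10),
                 paste(sample(BASES, spacer, replace = TRUE,
                              prob = base_probs), collapse = ""),
                 substr(halves, 11, 20))
        } else halves
        w <- nchar(site_seq)
        site_start <- summit - w %/% 2L
        site_strand <- sample(c("+", "-"), 1L)
        planted <- if (site_strand == "+") site_seq else revcomp(site_seq)
        substr(seq_c, site_start + 1L, site_start + w) <- planted
      }
      reg[[peak_i]] <- data.frame(
        name = sprintf("peak_%04d", peak_i),
        chrom = names(genome)[ci], summit = summit,
        chromatin_class = cls, motif_class = mcls, spacer = spacer,
        site_start = site_start, site_strand = site_strand,
        site_seq = site_seq, stringsAsFactors = FALSE
      )
    }
    genome[ci] <- seq_c
  }
  registry <- do.call(rbind, reg)
  list(genome = genome, chrom_lens = nchar(genome),
       registry = registry, cfg = cfg)
}

#' Simulate peak calls and per-peak read counts
#'
#' Builds a called interval around every registry summit (width uniform in
#' `peak_width_range`, summit at 35-65% of the width) and draws Poisson
#' ChIP / input read counts whose means follow the per-motif-class
#' reads-per-million model, so that mean enrichment ranks
#' UNSPLIT > SPACED > NO_MOTIF.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @return list with `peaks` (a `peak_set` with counts; enrichment not yet
#'   computed) and `truth` (the registry).
#' @export
simulate_peaks <- function(cfg, sim) {
  set.seed(stage_seed(cfg, 1))
  reg <- sim$registry
  n <- nrow(reg)
  if (is.null(reg) || n == 0L) {
    return(list(peaks = peak_set(character(0), integer(0), integer(0),
                                 name = character(0)),
                truth = reg))
  }
  w <- sample(cfg$peak_width_range[1]:cfg$peak_width_range[2], n,
              replace = TRUE)
  frac <- stats::runif(n, 0.35, 0.65)
  summit_offset <- pmin(pmax(as.integer(round(w * frac)), 1L), w - 1L)
  start <- reg$summit - summit_offset
  lens <- sim$chrom_lens[reg$chrom]
  start <- pmax(0L, pmin(start, lens - w))
  summit_offset <- reg$summit - start
  mu_rpm <- cfg$chip_rpm[reg$motif_class] *
    exp(stats::rnorm(n, 0, cfg$rpm_sdlog))
  chip <- stats::rpois(n, mu_rpm * cfg$chip_libsize / 1e6)
  input <- stats::rpois(n, cfg$input_rpm * cfg$input_libsize / 1e6)
  peaks <- peak_set(reg$chrom, start, start + w, name = reg$name,
                    summit_offset = summit_offset,
                    chip_count = chip, input_count = input,
                    chip_libsize = cfg$chip_libsize,
                    input_libsize = cfg$input_libsize,
                    label = "simulated")
  list(peaks = peaks, truth = reg)
}

#' Simulate gene annotation and chromatin-mark peak sets
#'
#' Every promoter-class locus receives a gene whose strand-aware -5/+2 kb
#' window covers the summit, plus active marks at the configured rates;
#' enhancer-class loci receive H3K4me1 (and friends) but no gene; unmarked
#' loci receive nothing. Locus spacing makes the three constructions
#' disjoint, so classification recovers the planted classes exactly.
#' Genes beyond the promoter loci (up to `n_genes`) are placed on an
#' annotation-only contig `chrU` so their windows cannot touch any peak.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @param gene_assignment optional named character vector mapping promoter
#'   peak names to gene ids (defaults to gene_0001, ... in peak order,
#'   with unbound genes continuing the series).
#' @return list with `genes` (gene_id, chrom, tss, strand, exon_length,
#'   bound_peak, motif_class), `marks` (named list of `peak_set`s),
#'   `chrom_lens` (including chrU).
#' @export
simulate_annotation <- function(cfg, sim, gene_assignment = NULL) {
  set.seed(stage_seed(cfg, 2))
  reg <- sim$registry
  prom <- reg[!is.null(reg) & reg$chromatin_class == "promoter", ,
              drop = FALSE]
  np <- nrow(prom)
  n_unbound <- max(0L, cfg$n_genes - np)
  all_ids <- sprintf("gene_%04d", seq_len(np + n_unbound))
  if (is.null(gene_assignment)) {
    gene_assignment <- stats::setNames(all_ids[seq_len(np)], prom$name)
  } else {
    if (!all(prom$name %in% names(gene_assignment))) {
      stop("gene_assignment must cover every promoter peak")
    }
    all_ids <- c(unname(gene_assignment[prom$name]),
                 setdiff(all_ids, gene_assignment[prom$name]))
  }
  strand <- sample(c("+", "-"), np, replace = TRUE)
  d <- ifelse(strand == "+",
              sample(-1000:3000, np, replace = TRUE),
              sample(-3000:1000, np, replace = TRUE))
  tss <- prom$summit + d
  bound <- data.frame(
    gene_id = unname(gene_assignment[prom$name]),
    chrom = prom$chrom, tss = tss, strand = strand,
    bound_peak = prom$name, motif_class = prom$motif_class,
    stringsAsFactors = FALSE
  )
  unbound <- if (n_unbound > 0L) data.frame(
    gene_id = all_ids[np + seq_len(n_unbound)],
    chrom = "chrU",
    tss = 6000L + (seq_len(n_unbound) - 1L) * 12000L,
    strand = sample(c("+", "-"), n_unbound, replace = TRUE),
    bound_peak = NA_character_, motif_class = "NO_MOTIF",
    stringsAsFactors = FALSE
  ) else NULL
  genes <- rbind(bound, unbound)
  genes$exon_length <- pmax(
    200L, as.integer(round(stats::rlnorm(nrow(genes), cfg$exon_meanlog,
                                         cfg$exon_sdlog))))
  mark_names <- names(cfg$mark_rates[[1]])
  marks <- lapply(mark_names, function(m) {
    rate <- vapply(cfg$mark_rates, `[[`, 0, m)[reg$chromatin_class]
    has <- stats::runif(nrow(reg)) < rate
    sub <- reg[has, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(peak_set(character(0), integer(0), integer(0),
                      name = character(0), label = m))
    }
    start <- pmax(0L, sub$summit - cfg$mark_halfwidth)
    peak_set(sub$chrom, start, sub$summit + cfg$mark_halfwidth,
             name = sprintf("%s_%s", m, sub$name), label = m)
  })
  names(marks) <- mark_names
  chrom_lens <- c(sim$chrom_lens,
                  chrU = max(1L, n_unbound) * 12000L + 6000L)
  list(genes = genes, marks = marks, chrom_lens = chrom_lens)
}

# Assign planted regulatory modes: UP_DEP genes are drawn preferentially
# from genes bound via an unsplit-motif promoter peak; other responsive
# modes are drawn uniformly from the rest.
assign_modes <- function(cfg, genes) {
  n <- nrow(genes)
  n_alt <- round(n * (1 - cfg$fraction_null))
  k <- n_alt %/% 4L
  mode <- stats::setNames(rep("UNCHANGED", n), genes$gene_id)
  pool_bu <- genes$gene_id[!is.na(genes$bound_peak) &
                             genes$motif_class == "UNSPLIT"]
  take_bu <- min(round(k * cfg$updep_bound_unsplit), length(pool_bu), k)
  updep <- sample(pool_bu, take_bu)
  rest <- setdiff(genes$gene_id, updep)
  extra <- sample(rest, k - take_bu)
  updep <- c(updep, extra)
  rest <- setdiff(rest, extra)
  for (m in c("UP_INDEP", "DOWN_DEP", "DOWN_INDEP")) {
    pick <- sample(rest, k)
    mode[pick] <- m
    rest <- setdiff(rest, pick)
  }
  mode[updep] <- "UP_DEP"
  data.frame(gene_id = genes$gene_id, mode = unname(mode[genes$gene_id]),
             stringsAsFactors = FALSE)
}

#' Simulate the WT/KO x mock/IR count matrix
#'
#' Gene baseline means are lognormal; IR multiplies the mean by the
#' genotype-specific fold of the gene's planted mode; counts are negative
#' binomial at the configured dispersion (Poisson when dispersion is 0).
#'
#' @param cfg a [sim_config()].
#' @param genes gene table from [simulate_annotation()].
#' @param modes optional data frame gene_id, mode; planted by
#'   `assign_modes` when NULL.
#' @param cell_type label written into the sample metadata.
#' @return list with `counts` (genes x samples), `meta` (sample metadata:
#'   sample_id, genotype, treatment, cell_type, replicate), `truth`
#'   (gene_id, mode, wt_fold, ko_fold, base_mean).
#' @export
simulate_counts <- function(cfg, genes, modes = NULL, cell_type = "B") {
  set.seed(stage_seed(cfg, 3))
  if (cfg$n_replicates < 2L || cfg$ko_replicates < 2L) {
    stop("need >= 2 replicates per condition")
  }
  if (is.null(modes)) modes <- assign_modes(cfg, genes)
  stopifnot(setequal(modes$gene_id, genes$gene_id))
  mode <- modes$mode[match(genes$gene_id, modes$gene_id)]
  meta <- do.call(rbind, lapply(c("WT", "KO"), function(g) {
    nrep <- if (g == "WT") cfg$n_replicates else cfg$ko_replicates
    expand.grid(genotype = g, treatment = c("mock", "IR"),
                replicate = seq_len(nrep), stringsAsFactors = FALSE)
  }))
  meta$cell_type <- cell_type
  meta$sample_id <- sprintf("%s_%s_%s_r%d", cell_type, meta$genotype,
                            meta$treatment, meta$replicate)
  base_mean <- stats::rlnorm(nrow(genes), cfg$base_meanlog, cfg$base_sdlog)
  fold_for <- function(geno) {
    f <- rep(1, nrow(genes))
    for (m in names(cfg$effects)) {
      f[mode == m] <- cfg$effects[[m]][[if (geno == "WT") "wt" else "ko"]]
    }
    f
  }
  wt_fold <- fold_for("WT")
  ko_fold <- fold_for("KO")
  counts <- matrix(0L, nrow(genes), nrow(meta),
                   dimnames = list(genes$gene_id, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    f <- if (meta$treatment[j] == "mock") 1 else
      if (meta$genotype[j] == "WT") wt_fold else ko_fold
    mu <- base_mean * f
    counts[, j] <- if (cfg$dispersion < 1e-12) {
      stats::rpois(nrow(genes), mu)
    } else {
      stats::rnbinom(nrow(genes), mu = mu, size = 1 / cfg$dispersion)
    }
  }
  truth <- data.frame(gene_id = genes$gene_id, mode = mode,
                      wt_fold = wt_fold, ko_fold = ko_fold,
                      base_mean = base_mean, stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, truth = truth)
}

#' Simulate a complete one- or two-cell-type study
#'
#' Runs all generator stages for each cell type. With two cell types a
#' shared "core" of `n_core` genes is planted: in both cell types these
#' genes own an unsplit-motif promoter peak and carry the UP_DEP mode;
#' `n_private` further genes per cell type are UP_DEP and bound-unsplit in
#' that cell type only; the remaining responsive genes are drawn from
#' disjoint per-cell-type pools so that no gene other than the core can be
#' dependent-and-unsplit-bound in both.
#'
#' @param cfg a [sim_config()].
#' @param cell_types character vector of cell-type labels (1 or 2).
#' @param n_core size of the shared core (two cell types only).
#' @param n_private per-cell-type private dependent genes.
#' @param dir optional directory; when given, all standard files are
#'   written under `dir/<cell_type>/` (genome.fa, peaks.narrowPeak,
#'   peak_counts.tsv, genes.tsv, marks/<mark>.bed, counts.tsv,
#'   samples.tsv) plus `truth.json`.
#' @return named list per cell type: `genome`, `chrom_lens`, `peaks`,
#'   `registry`, `genes`, `marks`, `counts`, `meta`, `modes`; plus
#'   `core_genes` when two cell types are simulated.
#' @export
simulate_study <- function(cfg, cell_types = "B", n_core = 50L,
                           n_private = c(20L, 30L), dir = NULL) {
  two <- length(cell_types) == 2L
  np_total <- cfg$n_genes
  ids <- sprintf("gene_%04d", seq_len(np_total))
  core <- if (two) ids[seq_len(n_core)] else character(0)
  priv <- if (two) list(ids[n_core + seq_len(n_private[1])],
                        ids[n_core + n_private[1] + seq_len(n_private[2])])
  else list(character(0), character(0))
  reserved <- c(core, unlist(priv))
  free <- setdiff(ids, reserved)
  # disjoint per-cell-type pools for generic responsive genes, plus a
  # shared filler pool (UNCHANGED everywhere) for the remaining
  # unsplit-bound promoter peaks
  n_fill <- min(length(free), max(50L, length(free) %/% 5L))
  filler <- free[seq_len(n_fill)]
  rest <- setdiff(free, filler)
  pools <- split(rest, rep(seq_along(cell_types),
                           length.out = length(rest)))
  out <- list()
  for (i in seq_along(cell_types)) {
    ct <- cell_types[i]
    cfg_ct <- cfg
    cfg_ct$seed <- stage_seed(cfg, 7919L * i)
    if (two) {
      cfg_ct$force_promoter_unsplit <-
        max(cfg$force_promoter_unsplit, n_core + n_private[i])
    }
    g <- simulate_genome(cfg_ct)
    pk <- simulate_peaks(cfg_ct, g)
    reg <- g$registry
    if (!two) {
      # single cell type: default gene assignment; responsive modes drawn
      # with the bound-unsplit preference for UP_DEP
      ann <- simulate_annotation(cfg_ct, g)
      set.seed(stage_seed(cfg_ct, 6))
      modes <- assign_modes(cfg_ct, ann$genes)
      cnt <- simulate_counts(cfg_ct, ann$genes, modes = modes,
                             cell_type = ct)
      out[[ct]] <- list(genome = g$genome, chrom_lens = ann$chrom_lens,
                        peaks = pk$peaks, registry = reg,
                        genes = ann$genes, marks = ann$marks,
                        counts = cnt$counts, meta = cnt$meta,
                        modes = cnt$truth)
      next
    }
    prom <- reg[reg$chromatin_class == "promoter", , drop = FALSE]
    prom_unsplit <- prom$name[prom$motif_class == "UNSPLIT"]
    prom_other <- setdiff(prom$name, prom_unsplit)
    forced <- c(core, priv[[i]])
    if (length(prom_unsplit) < length(forced)) {
      stop("not enough unsplit promoter peaks to host the planted core; ",
           "raise n_peaks or the promoter/unsplit rates")
    }
    set.seed(stage_seed(cfg_ct, 5))
    assign <- character(0)
    if (length(prom_unsplit)) {
      fill_n <- length(prom_unsplit) - length(forced)
      fill <- if (fill_n > 0L) filler[seq_len(min(fill_n, length(filler)))]
      else character(0)
      take <- c(forced, fill)[seq_len(length(prom_unsplit))]
      assign <- stats::setNames(take, prom_unsplit)
    }
    remaining <- setdiff(ids, assign)
    if (length(prom_other)) {
      pool_other <- setdiff(remaining, c(reserved, filler))
      assign <- c(assign, stats::setNames(
        pool_other[seq_len(length(prom_other))], prom_other))
    }
    ann <- simulate_annotation(cfg_ct, g, gene_assignment = assign)
    # planted modes: forced core/private UP_DEP; generic responsive genes
    # from this cell type's pool; everything else UNCHANGED
    set.seed(stage_seed(cfg_ct, 6))
    mode <- stats::setNames(rep("UNCHANGED", length(ids)), ids)
    mode[forced] <- "UP_DEP"
    pool <- intersect(pools[[i]], ann$genes$gene_id)
    n_alt <- max(0L, round(length(ids) * (1 - cfg$fraction_null)) -
                   length(forced))
    k <- min(n_alt %/% 4L, length(pool) %/% 4L)
    if (k > 0L) {
      pick <- sample(pool, 4L * k)
      mode[pick] <- rep(c("UP_DEP", "UP_INDEP", "DOWN_DEP", "DOWN_INDEP"),
                        each = k)
    }
    modes <- data.frame(gene_id = ann$genes$gene_id,
                        mode = unname(mode[ann$genes$gene_id]),
                        stringsAsFactors = FALSE)
    cnt <- simulate_counts(cfg_ct, ann$genes, modes = modes,
                           cell_type = ct)
    out[[ct]] <- list(genome = g$genome, chrom_lens = ann$chrom_lens,
                      peaks = pk$peaks, registry = reg,
                      genes = ann$genes, marks = ann$marks,
                      counts = cnt$counts, meta = cnt$meta,
                      modes = cnt$truth)
  }
  if (two) out$core_genes <- core
  if (!is.null(dir)) write_study(out, dir, cell_types)
  out
}

write_study <- function(study, dir, cell_types) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  for (ct in cell_types) {
    s <- study[[ct]]
    d <- file.path(dir, ct)
    dir.create(file.path(d, "marks"), recursive = TRUE,
               showWarnings = FALSE)
    write_genome(s$genome, file.path(d, "genome.fa"))
    write_regions(s$peaks, file.path(d, "peaks.narrowPeak"), "narrowPeak")
    write_tsv_file(s$peaks[, c("name", "chip_count", "input_count",
                               "chip_libsize", "input_libsize")],
                   file.path(d, "peak_counts.tsv"))
    write_tsv_file(s$genes, file.path(d, "genes.tsv"))
    for (m in names(s$marks)) {
      write_regions(s$marks[[m]], file.path(d, "marks", paste0(m, ".bed")),
                    "bed")
    }
    write_tsv_file(data.frame(gene_id = rownames(s$counts), s$counts,
                              check.names = FALSE),
                   file.path(d, "counts.tsv"))
    write_tsv_file(s$meta, file.path(d, "samples.tsv"))
    truth[[ct]] <- list(registry = s$registry, modes = s$modes)
  }
  if (!is.null(study$core_genes)) truth$core_genes <- study$core_genes
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  invisible(dir)
}
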