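# End-to-end pipeline: enrichment -> motif discovery -> scanning ->
# chromatin classification -> differential expression -> dependence ->
# integration, with every stage's table written to disk and a manifest
# recording a configuration hash and per-file checksums.

#' Pipeline run configuration
#'
#' All thresholds of the analysis in one place. Defaults are the study's:
#' per-match motif p-value 1e-4, DEG q < 0.05 with |log2FC| > 0.58 and
#' RPKM > 1, dependence ratio 1.5, promoter -5000/+2000, top 1000 peaks
#' for discovery.
#'
#' @param motif_pvalue per-match p-value threshold for the scanner.
#' @param deg_q,lfc,min_rpkm DEG thresholds.
#' @param dependence_ratio fold-ratio defining p53 dependence.
#' @param promoter_up,promoter_down promoter window, bp up/downstream.
#' @param top_n peaks used for de novo discovery.
#' @param flank scanning half-window around summits (bp).
#' @param discovery_flank half-window for discovery input sequences (bp).
#' @param motif_width,n_restarts,max_iter,tol ZOOPS-EM settings.
#' @param granularity p-value DP lattice width.
#' @param scan_pwm "discovered" to scan with the de novo motif, or a
#'   `pwm` object / path to a MEME file to scan with a fixed model.
#' @param seed seed for the discovery restarts.
#' @return list of class `run_config`.
#' @export
run_config <- function(motif_pvalue = 1e-4, deg_q = 0.05, lfc = 0.58,
                       min_rpkm = 1, dependence_ratio = 1.5,
                       promoter_up = 5000L, promoter_down = 2000L,
                       top_n = 1000L, flank = 300L, discovery_flank = 60L,
                       motif_width = 20L, n_restarts = 10L,
                       max_iter = 200L, tol = 1e-6, granularity = 1e-4,
                       scan_pwm = "discovered", seed = 1L) {
  cfg <- as.list(environment())
  num <- cfg[c("motif_pvalue", "deg_q", "lfc", "min_rpkm",
               "dependence_ratio", "promoter_up", "promoter_down",
               "top_n", "flank")]
  if (any(unlist(num) <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  canon <- config
  if (inherits(canon$scan_pwm, "pwm")) {
    canon$scan_pwm <- as.vector(canon$scan_pwm$probs)
  }
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(canon[order(names(canon))], tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on one sample's inputs
#'
#' Stages, in order: peak enrichment; de novo motif discovery on the
#' top-enriched peaks; spacer-variant scanning of all summit windows;
#' promoter/enhancer/unmarked classification against the chromatin marks;
#' differential expression (IR vs mock) within each genotype; the
#' dependence rule and regulatory modes; integration of binding and
#' regulation. Every table is written to `outdir` and `manifest.json`
#' records the configuration hash, row counts and md5 checksums (and a
#' combined `manifest_hash` that is identical across reruns with the same
#' inputs, seed and configuration).
#'
#' @param inputs named list of file paths: `genome` (FASTA), `peaks`
#'   (narrowPeak), `peak_counts` (TSV: name, chip_count, input_count,
#'   chip_libsize, input_libsize), `genes` (TSV: gene_id, chrom, tss,
#'   strand, exon_length), `marks` (named vector of BED paths, must
#'   include H3K4me1), `counts` (TSV genes x samples, first column
#'   gene_id), `meta` (TSV with sample_id, genotype, treatment).
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(inputs, config = run_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  msg <- function(...) message(sprintf(...))
  outputs <- character(0)
  records <- list()
  emit <- function(df, fname) {
    path <- file.path(outdir, fname)
    write_tsv_file(df, path)
    outputs <<- c(outputs, fname)
    records[[fname]] <<- nrow(df)
    path
  }

  loaded <- stage("load", {
    genome <- read_genome(inputs$genome)
    peaks <- read_regions(inputs$peaks, "narrowPeak")
    pc <- read_tsv_file(inputs$peak_counts)
    i <- match(peaks$name, pc$name)
    if (anyNA(i)) stop("peak_counts missing peaks")
    peaks$chip_count <- pc$chip_count[i]
    peaks$input_count <- pc$input_count[i]
    peaks$chip_libsize <- pc$chip_libsize[i]
    peaks$input_libsize <- pc$input_libsize[i]
    genes <- read_tsv_file(inputs$genes)
    counts_df <- read_tsv_file(inputs$counts)
    counts <- as.matrix(counts_df[, -1, drop = FALSE])
    rownames(counts) <- counts_df[[1]]
    meta <- read_tsv_file(inputs$meta)
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id)) stop("meta must describe every count column")
    marks <- lapply(inputs$marks, read_regions, format = "bed")
    list(genome = genome, peaks = peaks, genes = genes, counts = counts,
         meta = meta, marks = marks)
  })
  msg("loaded %d peaks, %d genes, %d samples", nrow(loaded$peaks),
      nrow(loaded$genes), ncol(loaded$counts))

  peaks <- stage("enrich", peak_enrichment(loaded$peaks))
  emit(peaks[, c("name", "chrom", "start", "end", "summit_offset",
                 "chip_count", "input_count", "enrichment")],
       "enrichment.tsv")

  disc <- stage("discover", {
    ranked <- peaks[!is.na(peaks$enrichment), , drop = FALSE]
    top <- top_peaks(ranked, config$top_n)
    seqs <- peak_flank_seqs(top, loaded$genome, config$discovery_flank)
    discover_motif(seqs, width = config$motif_width,
                   n_restarts = config$n_restarts,
                   max_iter = config$max_iter, tol = config$tol,
                   seed = config$seed)
  })
  write_meme(disc$pwm, file.path(outdir, "motif.meme"), "discovered")
  outputs <- c(outputs, "motif.meme")
  records[["motif.meme"]] <- 1L
  msg("discovered motif %s (IC %.1f bits)", pwm_consensus(disc$pwm),
      disc$information_content)

  hits <- stage("scan", {
    scan_model <- config$scan_pwm
    pwm20 <- if (inherits(scan_model, "pwm")) scan_model
    else if (identical(scan_model, "discovered")) disc$pwm
    else read_meme(scan_model)
    model <- build_spaced_pwm(pwm20)
    scan_peaks(peaks, loaded$genome, model, flank = config$flank,
               threshold = config$motif_pvalue,
               granularity = config$granularity)
  })
  emit(hits, "motif_hits.tsv")
  motif_cls <- classify_hits(hits)

  landscape <- stage("classify", {
    if (!"H3K4me1" %in% names(loaded$marks)) {
      stop("no H3K4me1 mark set supplied")
    }
    chrom_lens <- nchar(loaded$genome)
    missing <- setdiff(unique(loaded$genes$chrom), names(chrom_lens))
    if (length(missing)) {
      extra <- vapply(missing, function(ch) {
        max(loaded$genes$tss[loaded$genes$chrom == ch]) +
          config$promoter_up + config$promoter_down
      }, numeric(1))
      chrom_lens <- c(chrom_lens, extra)
    }
    windows <- promoter_windows(loaded$genes, chrom_lens,
                                config$promoter_up, config$promoter_down)
    cls <- classify_peaks(peaks, windows, loaded$marks)
    list(windows = windows, classes = cls$classes, counts = cls$counts,
         mark_pct = mark_overlap_summary(peaks, cls$classes, loaded$marks),
         motif_pct = motif_by_class(cls$classes, motif_cls$classes))
  })
  emit(landscape$classes, "peak_classes.tsv")
  emit(data.frame(class = rownames(landscape$mark_pct),
                  landscape$mark_pct, check.names = FALSE),
       "class_mark_overlap.tsv")
  msg("peak classes: %s",
      paste(names(landscape$counts), landscape$counts, collapse = ", "))

  de <- stage("de", {
    rp <- rpkm(loaded$counts, loaded$genes$exon_length[
      match(rownames(loaded$counts), loaded$genes$gene_id)])
    by_geno <- lapply(c("WT", "KO"), function(g) {
      sel <- loaded$meta$genotype == g
      nb_de_test(loaded$counts[, sel, drop = FALSE],
                 loaded$meta[sel, , drop = FALSE])
    })
    names(by_geno) <- c("WT", "KO")
    list(rpkm = rp, wt = by_geno$WT, ko = by_geno$KO)
  })
  emit(de$wt, "de_WT.tsv")
  emit(de$ko, "de_KO.tsv")

  modes <- stage("dependence", {
    wt_cols <- loaded$meta$genotype == "WT"
    degs <- call_degs(de$wt, de$rpkm[, wt_cols, drop = FALSE],
                      q_cut = config$deg_q, lfc = config$lfc,
                      min_rpkm = config$min_rpkm)
    regulatory_modes(de$wt, de$ko, degs, ratio = config$dependence_ratio)
  })
  emit(modes, "regulatory_modes.tsv")
  msg("DEGs: %d up, %d down",
      sum(modes$mode %in% c("UP_DEP", "UP_INDEP")),
      sum(modes$mode %in% c("DOWN_DEP", "DOWN_INDEP")))

  integ <- stage("integrate", {
    links <- link_genes_to_peaks(loaded$genes, peaks, landscape$windows,
                                 hits)
    xt <- regulatory_crosstab(links, modes)
    core <- core_candidates(modes, links)
    list(links = links, crosstab = xt, core = core)
  })
  emit(integ$links, "gene_peak_links.tsv")
  xt <- integ$crosstab
  emit(data.frame(mode = rownames(xt$counts), xt$counts,
                  check.names = FALSE), "crosstab_counts.tsv")
  emit(data.frame(gene_id = integ$core), "core_candidates.tsv")

  manifest <- stage("manifest", {
    files <- file.path(outdir, outputs)
    sums <- tools::md5sum(files)
    names(sums) <- outputs
    lines <- sprintf("%s:%s", outputs, sums)
    tf <- tempfile()
    writeLines(sort(lines), tf)
    mh <- unname(tools::md5sum(tf))
    unlink(tf)
    list(package = "p53response",
         version = as.character(utils::packageVersion("p53response")),
         config_hash = config_hash(config),
         outputs = as.list(sums),
         records = records,
         manifest_hash = mh)
  })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  msg("wrote %d tables to %s (manifest %s)", length(outputs), outdir,
      manifest$manifest_hash)

  invisible(list(peaks = peaks, discovery = disc, hits = hits,
                 motif_classes = motif_cls, landscape = landscape,
                 de = de, modes = modes, integration = integ,
                 manifest = manifest))
}
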