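# Expression quantification and differential-expression calling: RPKM,
# a simplified negative-binomial Wald test (median-of-ratios size factors,
# method-of-moments dispersion), the DEG thresholds, the genotype
# (p53) dependence rule, Spearman clustering of samples, and Fisher
# gene-set enrichment.

REGULATORY_MODES <- c("UP_DEP", "UP_INDEP", "DOWN_DEP", "DOWN_INDEP",
                      "UNCHANGED")

#' Reads per kilobase of exon per million exon-mapped reads
#'
#' `rpkm[g, s] = counts[g, s] * 1e9 / (exon_lengths[g] * totals[s])`,
#' where the per-sample totals are the reads mapping to exons only.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param exon_lengths per-gene exonic length in bp (> 0).
#' @param totals per-sample exon-mapped library sizes (> 0); defaults to
#'   the column sums of `counts`.
#' @return matrix of RPKM values with the dimnames of `counts`.
#' @export
rpkm <- function(counts, exon_lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(exon_lengths <= 0)) stop("exon lengths must be > 0")
  if (any(totals <= 0)) stop("exon-mapped totals must be > 0")
  if (length(exon_lengths) != nrow(counts)) {
    stop("exon_lengths must have one entry per gene")
  }
  sweep(counts / exon_lengths, 2L, totals, "/") * 1e9
}

# Median-of-ratios size factors (a la DESeq): ratio of each sample to the
# gene-wise geometric mean, median over genes positive in every sample.
size_factors <- function(counts) {
  logs <- log(counts)
  logmeans <- rowMeans(logs)
  ok <- is.finite(logmeans)
  if (!any(ok)) stop("no gene has positive counts in every sample")
  apply(counts, 2L, function(col) {
    exp(stats::median((log(col) - logmeans)[ok & col > 0]))
  })
}

#' Simplified negative-binomial differential-expression test
#'
#' A transparent stand-in for a full NB GLM engine: counts are normalised
#' with median-of-ratios size factors; the log2 fold change compares the
#' group means with a pseudo-mean of 0.5; a gene-wise NB dispersion is
#' estimated by the method of moments within groups (floored at 1e-8); a
#' Wald statistic on the log2 scale (delta method) is referred to a t
#' distribution with n1 + n2 - 2 degrees of freedom; BH adjustment is
#' applied across genes passing an independent-filter floor of mean
#' normalised count >= 1. Externally computed DE tables (gene_id, log2fc,
#' qvalue) can be imported instead via [import_de()].
#'
#' @param counts genes x samples integer matrix (rownames = gene ids).
#' @param meta data frame with one row per sample (in column order of
#'   `counts`) and a `treatment` column.
#' @param treatment_ref,treatment_alt levels of `meta$treatment` to
#'   contrast; the fold change is alt (e.g. IR) over ref (e.g. mock).
#' @param min_mean independent-filtering floor on the mean normalised
#'   count (default 1); filtered genes get NA p and q.
#' @return data frame: `gene_id`, `base_mean`, `log2fc`, `stat`, `pvalue`,
#'   `qvalue`.
#' @export
nb_de_test <- function(counts, meta, treatment_ref = "mock",
                       treatment_alt = "IR", min_mean = 1) {
  counts <- as.matrix(counts)
  if (nrow(meta) != ncol(counts)) stop("meta must describe every sample")
  g1 <- which(meta$treatment == treatment_ref)
  g2 <- which(meta$treatment == treatment_alt)
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("need >= 2 replicates on each side of the contrast")
  }
  sf <- size_factors(counts[, c(g1, g2), drop = FALSE])
  norm <- sweep(counts[, c(g1, g2), drop = FALSE], 2L, sf, "/")
  i1 <- seq_along(g1)
  i2 <- length(g1) + seq_along(g2)
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  v1 <- apply(norm[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(norm[, i2, drop = FALSE], 1L, stats::var)
  # method-of-moments NB dispersion, pooled over the two groups
  a1 <- (v1 - m1) / m1^2
  a2 <- (v2 - m2) / m2^2
  disp <- pmax((a1 * n1 + a2 * n2) / (n1 + n2), 1e-8)
  disp[!is.finite(disp)] <- 1e-8
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  # delta-method variance of log2(mean + 0.5) under var(count)=mu+disp*mu^2
  vlog <- function(m, n) (m + disp * m^2) / n / (log(2) * (m + 0.5))^2
  se <- sqrt(vlog(m1, n1) + vlog(m2, n2))
  stat <- log2fc / se
  pvalue <- 2 * stats::pt(-abs(stat), df = n1 + n2 - 2)
  pvalue[se == 0] <- 1
  base_mean <- (m1 + m2) / 2
  tested <- base_mean >= min_mean
  pvalue[!tested] <- NA_real_
  qvalue <- rep(NA_real_, length(pvalue))
  qvalue[tested] <- stats::p.adjust(pvalue[tested], method = "BH")
  data.frame(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = base_mean, log2fc = log2fc, stat = stat,
    pvalue = pvalue, qvalue = qvalue, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import an externally computed differential-expression table
#'
#' @param path TSV with at least columns gene_id, log2fc, qvalue.
#' @return data frame usable wherever [nb_de_test()] output is.
#' @export
import_de <- function(path) {
  de <- read_tsv_file(path)
  need <- c("gene_id", "log2fc", "qvalue")
  if (!all(need %in% names(de))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  de
}

#' Call differentially expressed genes
#'
#' UP: q < 0.05 and log2 fold change > `lfc`; DOWN: q < 0.05 and log2 fold
#' change < -`lfc`; both additionally require an RPKM above
#' `min_rpkm` in at least one sample. All inequalities are strict.
#'
#' @param de data frame from [nb_de_test()] or [import_de()].
#' @param rpkm_mat genes x samples RPKM matrix (rownames = gene ids) for
#'   the expression filter.
#' @param q_cut,lfc,min_rpkm thresholds (defaults 0.05, 0.58, 1).
#' @return list with character vectors `up` and `down` of gene ids.
#' @export
call_degs <- function(de, rpkm_mat, q_cut = 0.05, lfc = 0.58, min_rpkm = 1) {
  max_rpkm <- apply(rpkm_mat, 1L, max)[de$gene_id]
  if (anyNA(max_rpkm)) stop("rpkm_mat must cover every gene in the DE table")
  ok <- !is.na(de$qvalue) & de$qvalue < q_cut & max_rpkm > min_rpkm
  list(up = de$gene_id[ok & de$log2fc > lfc],
       down = de$gene_id[ok & de$log2fc < -lfc])
}

#' p53-dependence of a differentially expressed gene
#'
#' An up-regulated wild-type DEG is p53-dependent when its fold induction
#' is at least `ratio` times higher than in the knockout:
#' `2^(wt_log2fc - ko_log2fc) >= ratio`. A down-regulated DEG is dependent
#' when its fold repression is at least `ratio` times lower:
#' `2^(ko_log2fc - wt_log2fc) >= ratio`. Genes missing from the knockout
#' contrast are treated as unresponsive there (`ko_log2fc = 0`), which
#' biases toward dependence; pass `na_ko` to change that.
#'
#' @param wt_log2fc,ko_log2fc log2 fold changes (IR vs mock) in wild type
#'   and knockout (vectorised).
#' @param direction "up" or "down" (vectorised or scalar).
#' @param ratio dependence threshold on the linear fold-change scale
#'   (default 1.5, inclusive).
#' @param na_ko value substituted for missing knockout fold changes.
#' @return character vector of "DEP"/"INDEP".
#' @export
classify_dependence <- function(wt_log2fc, ko_log2fc, direction,
                                ratio = 1.5, na_ko = 0) {
  ko_log2fc[is.na(ko_log2fc)] <- na_ko
  direction <- rep_len(direction, length(wt_log2fc))
  if (!all(direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'")
  }
  delta <- ifelse(direction == "up",
                  wt_log2fc - ko_log2fc, ko_log2fc - wt_log2fc)
  ifelse(2^delta >= ratio, "DEP", "INDEP")
}

#' Assign every gene its regulatory mode
#'
#' Combines WT DEG calls with the dependence rule into one of UP_DEP,
#' UP_INDEP, DOWN_DEP, DOWN_INDEP, UNCHANGED.
#'
#' @param de_wt,de_ko DE tables for the IR-vs-mock contrast in wild type
#'   and knockout.
#' @param degs list from [call_degs()] on the WT table.
#' @param ratio dependence threshold.
#' @return data frame `gene_id`, `mode`, `wt_log2fc`, `ko_log2fc`.
#' @export
regulatory_modes <- function(de_wt, de_ko, degs, ratio = 1.5) {
  ko <- de_ko$log2fc[match(de_wt$gene_id, de_ko$gene_id)]
  mode <- rep("UNCHANGED", nrow(de_wt))
  up <- de_wt$gene_id %in% degs$up
  down <- de_wt$gene_id %in% degs$down
  if (any(up)) {
    dep <- classify_dependence(de_wt$log2fc[up], ko[up], "up", ratio)
    mode[up] <- ifelse(dep == "DEP", "UP_DEP", "UP_INDEP")
  }
  if (any(down)) {
    dep <- classify_dependence(de_wt$log2fc[down], ko[down], "down", ratio)
    mode[down] <- ifelse(dep == "DEP", "DOWN_DEP", "DOWN_INDEP")
  }
  data.frame(gene_id = de_wt$gene_id, mode = mode,
             wt_log2fc = de_wt$log2fc, ko_log2fc = ko,
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of samples by Spearman correlation
#'
#' Restricts to expressed genes (RPKM > `min_rpkm` in at least one
#' sample), computes pairwise distances 1 - Spearman's rho between
#' samples, and clusters them by average-linkage agglomeration. Samples
#' are ordered by id beforehand so the tree is deterministic.
#'
#' @param rpkm_mat genes x samples RPKM matrix with column names.
#' @param min_rpkm expressed-gene floor (default 1).
#' @return an `hclust` object.
#' @export
spearman_cluster <- function(rpkm_mat, min_rpkm = 1) {
  if (ncol(rpkm_mat) < 2L) stop("need >= 2 samples")
  rpkm_mat <- rpkm_mat[, order(colnames(rpkm_mat)), drop = FALSE]
  keep <- apply(rpkm_mat, 1L, max) > min_rpkm
  x <- rpkm_mat[keep, , drop = FALSE]
  const <- apply(x, 2L, function(col) stats::var(rank(col)) == 0)
  if (any(const)) {
    stop("sample(s) with constant expression ranks: ",
         paste(colnames(x)[const], collapse = ", "))
  }
  rho <- stats::cor(x, method = "spearman")
  stats::hclust(stats::as.dist(1 - rho), method = "average")
}

#' One-sided Fisher (hypergeometric) gene-set enrichment
#'
#' Gene sets are intersected with the universe and filtered to sizes
#' greater than `min_size` and smaller than `max_size`; each surviving set
#' gets an upper-tail hypergeometric p-value for its overlap with the
#' query genes.
#'
#' @param genes query gene set (must be a subset of `universe`).
#' @param universe all testable genes.
#' @param sets named list of gene-id vectors.
#' @param min_size,max_size exclusive size bounds within the universe
#'   (defaults 10 and 2000).
#' @return data frame: set, set_size, overlap, pvalue; one row per
#'   surviving set.
#' @export
geneset_enrichment <- function(genes, universe, sets,
                               min_size = 10L, max_size = 2000L) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (!all(genes %in% universe)) {
    stop("query genes must be a subset of the universe")
  }
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sizes <- vapply(sets, length, 0L)
  keep <- sizes > min_size & sizes < max_size
  sets <- sets[keep]
  N <- length(universe)
  n <- length(genes)
  res <- lapply(names(sets), function(nm) {
    m <- length(sets[[nm]])
    k <- length(intersect(genes, sets[[nm]]))
    data.frame(set = nm, set_size = m, overlap = k,
               pvalue = stats::phyper(k - 1L, m, N - m, n,
                                      lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  if (!length(res)) {
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), pvalue = numeric(0)))
  }
  do.call(rbind, res)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, genes; tab-separated).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(fields, function(f) f[-(1:2)])
  names(out) <- vapply(fields, `[`, "", 1L)
  out
}
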