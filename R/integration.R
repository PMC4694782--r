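# Joining the binding and expression layers: which genes carry a peak in
# their promoter window, with which motif class, and how that crosses with
# the regulatory mode; the intersection across cell types defines the core
# response.

#' Link genes to their best promoter peak
#'
#' A gene is "bound" when at least one peak overlaps its strand-aware
#' promoter window. Among several overlapping peaks the one whose best
#' motif hit has the lowest p-value wins, then the highest enrichment,
#' then name order; the gene inherits that peak's motif class.
#'
#' @param genes data frame with `gene_id` (and whatever else; only the id
#'   is used here).
#' @param peaks a `peak_set`.
#' @param windows a `peak_set` of promoter windows named by gene_id (from
#'   [promoter_windows()]).
#' @param hits per-peak best-hit table from [scan_peaks()].
#' @param min_bp minimum overlap in bp.
#' @return data frame, one row per gene: `gene_id`, `peak_name` (NA when
#'   unbound), `motif_class` (NO_MOTIF when unbound), `motif_pvalue`,
#'   `spacer`.
#' @export
link_genes_to_peaks <- function(genes, peaks, windows, hits, min_bp = 1L) {
  stopifnot(all(genes$gene_id %in% windows$name))
  lev <- unique(c(windows$chrom, peaks$chrom))
  ov <- GenomicRanges::findOverlaps(
    peaks_to_granges(windows, lev), peaks_to_granges(peaks, lev),
    minoverlap = min_bp
  )
  wi <- S4Vectors::queryHits(ov)
  pi <- S4Vectors::subjectHits(ov)
  hp <- hits$pvalue[match(peaks$name[pi], hits$peak_name)]
  cand <- data.frame(
    gene_id = windows$name[wi],
    peak_name = peaks$name[pi],
    pvalue = ifelse(is.na(hp), Inf, hp),
    enrichment = peaks$enrichment[pi],
    stringsAsFactors = FALSE
  )
  cand <- cand[order(cand$gene_id, cand$pvalue, -xtfrm(cand$enrichment),
                     cand$peak_name), ]
  cand <- cand[!duplicated(cand$gene_id), ]
  i <- match(genes$gene_id, cand$gene_id)
  peak_name <- cand$peak_name[i]
  hrow <- match(peak_name, hits$peak_name)
  spacer <- hits$spacer[hrow]
  motif_class <- ifelse(is.na(peak_name), "NO_MOTIF",
                        ifelse(is.na(spacer), "NO_MOTIF",
                               ifelse(spacer == 0L, "UNSPLIT", "SPACED")))
  data.frame(
    gene_id = genes$gene_id,
    peak_name = peak_name,
    motif_class = motif_class,
    motif_pvalue = hits$pvalue[hrow],
    spacer = spacer,
    stringsAsFactors = FALSE
  )
}

#' Cross-tabulate regulatory mode by motif class for bound genes
#'
#' @param links data frame from [link_genes_to_peaks()].
#' @param modes data frame `gene_id`, `mode` from [regulatory_modes()].
#' @return list with `counts` and `percent` (row percentages) matrices,
#'   modes x motif classes, over bound genes only.
#' @export
regulatory_crosstab <- function(links, modes) {
  if (!all(links$gene_id %in% modes$gene_id)) {
    stop("every linked gene needs a regulatory mode")
  }
  mode <- modes$mode[match(links$gene_id, modes$gene_id)]
  bound <- !is.na(links$peak_name)
  counts <- table(
    factor(mode[bound], levels = REGULATORY_MODES),
    factor(links$motif_class[bound],
           levels = c("NO_MOTIF", "SPACED", "UNSPLIT"))
  )
  counts <- unclass(counts)
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs == 0, NA, rs)
  list(counts = counts, percent = percent,
       n_bound = sum(bound), n_genes = nrow(links))
}

#' Fold change by regulatory category and motif class
#'
#' Summarises the WT log2 fold change per (mode, motif class) group and
#' runs pairwise pooled-variance t-tests between all groups with at least
#' two genes (singleton groups are summarised but excluded from testing).
#'
#' @param modes data frame from [regulatory_modes()] (needs `gene_id`,
#'   `mode`, `wt_log2fc`).
#' @param links data frame from [link_genes_to_peaks()].
#' @param include_modes which modes to summarise (default the four DEG
#'   modes).
#' @return list with `summaries`, `tests` (from [group_compare()]) and
#'   `excluded` (groups of size < 2).
#' @export
fc_by_category <- function(modes, links,
                           include_modes = c("UP_DEP", "UP_INDEP",
                                             "DOWN_DEP", "DOWN_INDEP")) {
  mc <- links$motif_class[match(modes$gene_id, links$gene_id)]
  sel <- modes$mode %in% include_modes & !is.na(mc)
  grp <- paste(modes$mode[sel], mc[sel], sep = ".")
  vals <- split(modes$wt_log2fc[sel], grp)
  small <- vapply(vals, length, 0L) < 2L
  excluded <- data.frame(group = names(vals)[small],
                         n = vapply(vals[small], length, 0L))
  vals <- vals[!small]
  if (length(vals) < 2L) {
    return(list(summaries = NULL, tests = NULL, excluded = excluded))
  }
  gc <- group_compare(vals)
  list(summaries = gc$summaries, tests = gc$tests, excluded = excluded)
}

#' Core response shared between two cell types
#'
#' Intersects the gene sets that are p53-dependently up-regulated and
#' bound via an unsplit response element in each of two cell types.
#'
#' @param set_a,set_b character vectors of gene ids (computed by the same
#'   pipeline settings in the two cell types).
#' @return list: `core` (the intersection), `fraction_a`, `fraction_b`
#'   (share of each input covered by the core; 0 for an empty input).
#' @export
core_response <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  core <- intersect(set_a, set_b)
  frac <- function(s) if (length(s) == 0L) 0 else length(core) / length(s)
  list(core = sort(core), fraction_a = frac(set_a), fraction_b = frac(set_b))
}

#' Genes up-regulated p53-dependently and bound via the unsplit motif
#'
#' Convenience selector feeding [core_response()].
#'
#' @param modes data frame from [regulatory_modes()].
#' @param links data frame from [link_genes_to_peaks()].
#' @return character vector of gene ids.
#' @export
core_candidates <- function(modes, links) {
  mc <- links$motif_class[match(modes$gene_id, links$gene_id)]
  bound <- !is.na(links$peak_name[match(modes$gene_id, links$gene_id)])
  sort(modes$gene_id[modes$mode == "UP_DEP" & bound &
                       !is.na(mc) & mc == "UNSPLIT"])
}
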