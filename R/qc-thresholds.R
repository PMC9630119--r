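# Default QC filter parameters for the two scRNA-seq platforms.

# Natural domain of each Smart-seq2 metric (used by the synthetic generator
# to decide which side of an interval a violation can fall on).
.smartseq_metric_domains <- list(
  reads             = c(0, Inf),
  genes             = c(0, Inf),
  mean_read_length  = c(0, Inf),
  mismatch_rate     = c(0, 1),
  pct_unique_mapped = c(0, 100),
  pct_multimapped   = c(0, 100),
  pct_too_short     = c(0, 100),
  frac_ercc         = c(0, 1),
  frac_mito         = c(0, 1)
)

.smartseq_metrics <- names(.smartseq_metric_domains)

#' Smart-seq2 per-cell QC thresholds
#'
#' Closed intervals `[lo, hi]` for the nine per-cell quality metrics of the
#' plate-based pipeline. A cell passes QC iff every metric lies inside its
#' interval, bounds inclusive. Defaults: reads in `[20000, 4e6]`, detected
#' genes in `[1000, 6500]`, mean trimmed read length in `[180, 200]` bases,
#' alignment mismatch rate in `[0.15, 0.5]`, uniquely mapped percent in
#' `[68, 100]`, multimapped percent in `[2.3, 7.7]`, too-short percent in
#' `[0, 17]`, ERCC spike-in fraction in `[0, 0.011]` and mitochondrial
#' fraction in `[0, 0.006]`.
#'
#' Two conventions are taken as printed in the source workflow and flagged
#' here rather than "corrected": the mismatch-rate interval has a lower
#' bound (unusual for a contamination-style metric), and the ERCC /
#' mitochondrial bounds are interpreted on the 0-1 fraction scale. Both are
#' plain arguments, so alternative readings are one call away.
#'
#' @param ... named overrides, each a numeric `c(lo, hi)`.
#' @return Named list of length-2 numeric intervals, class `qc_thresholds`.
#' @examples
#' th <- smartseq_thresholds(genes = c(500, 8000))
#' th$genes
#' @export
smartseq_thresholds <- function(...) {
  th <- list(
    reads             = c(20000, 4e6),
    genes             = c(1000, 6500),
    mean_read_length  = c(180, 200),
    mismatch_rate     = c(0.15, 0.5),
    pct_unique_mapped = c(68, 100),
    pct_multimapped   = c(2.3, 7.7),
    pct_too_short     = c(0, 17),
    frac_ercc         = c(0, 0.011),
    frac_mito         = c(0, 0.006)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(th))
    if (length(bad)) stop("unknown QC metric(s): ", paste(bad, collapse = ", "))
    for (m in names(dots)) {
      v <- as.numeric(dots[[m]])
      if (length(v) != 2L || anyNA(v) || v[1] > v[2])
        stop("threshold for '", m, "' must be c(lo, hi) with lo <= hi")
      th[[m]] <- v
    }
  }
  structure(th, class = "qc_thresholds")
}

#' Droplet (10x) filter parameters
#'
#' Parameters of the droplet-platform filter chain: genes expressed in fewer
#' than `min_cells_per_gene` cells are dropped first, then cells failing any
#' of the per-cell rules are removed. Upper bounds are strict (a cell with
#' `max_umi` UMIs is removed; a cell with exactly `min_genes_per_cell`
#' detected genes is kept), and removal on the mitochondrial fraction
#' requires strictly exceeding `max_frac_mito`. The UMI and gene caps vary
#' by sequencing batch in the source workflow (30000/6000, 50000/8000,
#' 20000/none, 25000/8000) and are therefore configuration, not code.
#'
#' @param min_cells_per_gene minimum cells a gene must appear in (default 3).
#' @param min_genes_per_cell minimum detected genes per cell (default 200).
#' @param max_frac_mito maximum mitochondrial count fraction (default 0.10).
#' @param max_umi strict per-cell UMI cap, or `NULL` for none.
#' @param max_genes strict per-cell detected-gene cap, or `NULL` for none.
#' @return List of class `droplet_params`.
#' @export
droplet_params <- function(min_cells_per_gene = 3, min_genes_per_cell = 200,
                           max_frac_mito = 0.10, max_umi = 30000,
                           max_genes = 6000) {
  for (v in list(min_cells_per_gene, min_genes_per_cell, max_frac_mito)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0) stop("bounds must be single non-negative numbers")
  }
  if (!is.null(max_umi) && (!is.numeric(max_umi) || max_umi <= 0)) stop("max_umi must be positive or NULL")
  if (!is.null(max_genes) && (!is.numeric(max_genes) || max_genes <= 0)) stop("max_genes must be positive or NULL")
  structure(list(
    min_cells_per_gene = min_cells_per_gene,
    min_genes_per_cell = min_genes_per_cell,
    max_frac_mito = max_frac_mito,
    max_umi = max_umi,
    max_genes = max_genes
  ), class = "droplet_params")
}
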