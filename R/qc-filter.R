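# Per-cell QC filter chains for the plate-based (Smart-seq2) and droplet
# platforms, with per-metric failure attribution.

#' Apply the nine-metric Smart-seq2 QC filter chain
#'
#' A cell is kept iff every metric lies inside its closed threshold
#' interval (bounds inclusive: a cell with exactly 20000 reads passes the
#' default read filter). Output order preserves input order, and the
#' operation is idempotent: re-filtering the kept cells removes none.
#'
#' @param table `data.frame` with a `cell_id` column and the nine metric
#'   columns named as in [smartseq_thresholds()].
#' @param thresholds a [smartseq_thresholds()] object.
#' @return List with `kept` (character vector of kept cell ids, input
#'   order) and `report` (class `qc_report`): input/kept/removed counts,
#'   per-metric failure counts, and the removed cells with the metrics
#'   each failed.
#' @examples
#' tab <- generate_qc_table(50, list(genes = 4), seed = 2)
#' res <- apply_smartseq_filters(tab)
#' res$report
#' @export
apply_smartseq_filters <- function(table, thresholds = smartseq_thresholds()) {
  metrics <- names(thresholds)
  miss <- setdiff(c("cell_id", metrics), names(table))
  if (length(miss)) stop("QC table is missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(table)
  fail <- matrix(FALSE, n, length(metrics), dimnames = list(NULL, metrics))
  for (m in metrics) {
    v <- table[[m]]
    if (!is.numeric(v)) stop("metric '", m, "' is non-numeric")
    b <- thresholds[[m]]
    fail[, m] <- is.na(v) | v < b[1] | v > b[2]
  }
  pass <- rowSums(fail) == 0L
  removed <- data.frame(
    cell_id = table$cell_id[!pass],
    failed_metrics = apply(fail[!pass, , drop = FALSE], 1, function(f)
      paste(metrics[f], collapse = ";")),
    stringsAsFactors = FALSE
  )
  report <- structure(list(
    n_input = n, n_kept = sum(pass), n_removed = sum(!pass),
    metric_failures = colSums(fail), removed = removed
  ), class = "qc_report")
  list(kept = table$cell_id[pass], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_kept, "/", x$n_input, " cells kept (",
      x$n_removed, " removed)\n", sep = "")
  mf <- x$metric_failures[x$metric_failures > 0]
  if (length(mf)) {
    cat("  failures per metric:\n")
    for (m in names(mf)) cat("    ", m, ": ", mf[[m]], "\n", sep = "")
  }
  invisible(x)
}

#' Apply the droplet-platform filter chain
#'
#' Fixed order: genes expressed (count > 0) in fewer than
#' `min_cells_per_gene` cells are removed first; then cells are removed if
#' their detected-gene count (recomputed on the gene-filtered matrix)
#' falls below `min_genes_per_cell`, their mitochondrial count fraction
#' strictly exceeds `max_frac_mito`, or their total UMI count or detected
#' genes reach the strict caps (`>= max_umi`, `>= max_genes`). A cell with
#' exactly `min_genes_per_cell` detected genes or exactly `max_frac_mito`
#' mitochondrial fraction is kept. Mitochondrial genes are recognised by
#' the `mt-` prefix (case-insensitive).
#'
#' @param x an [expr_matrix()] or a genes x cells count matrix with
#'   dimnames.
#' @param params a [droplet_params()] object.
#' @return List with `matrix` (filtered [expr_matrix()]) and `report`
#'   (class `qc_report`; metric failure counts for `min_genes`,
#'   `frac_mito`, `max_umi`, `max_genes`, plus `genes_removed`).
#' @export
apply_droplet_filters <- function(x, params = droplet_params()) {
  em <- if (inherits(x, "expr_matrix")) x else
    expr_matrix(x, data.frame(cell_id = colnames(x)))
  counts <- em$counts
  if (length(counts@x) && any(counts@x < 0)) stop("counts must be non-negative")
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty matrix")
  n_input <- ncol(counts)

  gene_keep <- Matrix::rowSums(counts > 0) >= params$min_cells_per_gene
  counts <- counts[gene_keep, , drop = FALSE]

  detected <- Matrix::colSums(counts > 0)
  umi <- Matrix::colSums(counts)
  mito <- grepl("^mt-", rownames(counts), ignore.case = TRUE)
  frac_mito <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(umi, 1) else rep(0, ncol(counts))

  fail <- cbind(
    min_genes = detected < params$min_genes_per_cell,
    frac_mito = frac_mito > params$max_frac_mito,
    max_umi = if (is.null(params$max_umi)) rep(FALSE, ncol(counts)) else umi >= params$max_umi,
    max_genes = if (is.null(params$max_genes)) rep(FALSE, ncol(counts)) else detected >= params$max_genes
  )
  pass <- rowSums(fail) == 0L
  removed <- data.frame(
    cell_id = colnames(counts)[!pass],
    failed_metrics = apply(fail[!pass, , drop = FALSE], 1, function(f)
      paste(colnames(fail)[f], collapse = ";")),
    stringsAsFactors = FALSE
  )
  out <- expr_matrix(counts[, pass, drop = FALSE],
                     em$cells[pass, , drop = FALSE])
  report <- structure(list(
    n_input = n_input, n_kept = sum(pass), n_removed = sum(!pass),
    metric_failures = c(colSums(fail), genes_removed = sum(!gene_keep)),
    removed = removed
  ), class = "qc_report")
  list(matrix = out, report = report)
}

#' Remove named genes from an expression matrix
#'
#' Used to strip rRNA-contamination indicator genes (`Gm42418`,
#' `AY036118`) from droplet matrices. Genes absent from the matrix are
#' ignored with a note; cells are untouched.
#'
#' @param x an [expr_matrix()].
#' @param genes character vector of gene names to drop.
#' @return The filtered [expr_matrix()].
#' @export
remove_genes <- function(x, genes = c("Gm42418", "AY036118")) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!length(genes)) return(x)
  absent <- setdiff(genes, rownames(x$counts))
  if (length(absent))
    message("remove_genes: not present, ignored: ", paste(absent, collapse = ", "))
  keep <- !(rownames(x$counts) %in% genes)
  expr_matrix(x$counts[keep, , drop = FALSE], x$cells)
}
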