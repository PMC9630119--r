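# Plain-text IO: MatrixMarket + TSV sidecars or dense CSV for count
# matrices, CSV for point patterns, JSON for results. All outputs are
# versioned text so runs diff cleanly.

#' Write a count matrix with metadata sidecars
#'
#' `mtx` layout: `matrix.mtx` (MatrixMarket), `genes.tsv` (one gene per
#' line, header `gene`), `cells.tsv` (tab-separated cell metadata). `csv`
#' layout: `counts.csv` (dense, first column `gene`) and `cells.csv`.
#' Integer counts round-trip exactly through [read_counts()].
#'
#' @param x an [expr_matrix()].
#' @param dir output directory (created if needed).
#' @param format `"mtx"` (default) or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir, format = c("mtx", "csv")) {
  stopifnot(inherits(x, "expr_matrix"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "mtx") {
    Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
    utils::write.table(data.frame(gene = rownames(x$counts)),
                       file.path(dir, "genes.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(x$cells, file.path(dir, "cells.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    dense <- as.matrix(x$counts)
    utils::write.csv(data.frame(gene = rownames(dense), dense,
                                check.names = FALSE),
                     file.path(dir, "counts.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(x$cells, file.path(dir, "cells.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param dir directory holding either the `mtx` or `csv` layout.
#' @return An [expr_matrix()].
#' @export
read_counts <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (file.exists(mtx)) {
    counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                               stringsAsFactors = FALSE)$gene
    cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                               stringsAsFactors = FALSE)
    if (length(genes) != nrow(counts))
      stop("genes.tsv has ", length(genes), " genes but matrix has ",
           nrow(counts), " rows")
    if (nrow(cells) != ncol(counts))
      stop("cells.tsv has ", nrow(cells), " cells but matrix has ",
           ncol(counts), " columns")
    dimnames(counts) <- list(genes, cells$cell_id)
    return(expr_matrix(counts, cells))
  }
  csv <- file.path(dir, "counts.csv")
  if (!file.exists(csv)) stop("no matrix.mtx or counts.csv under ", dir)
  dense <- utils::read.csv(csv, check.names = FALSE, stringsAsFactors = FALSE)
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  m <- as.matrix(dense[, -1, drop = FALSE])
  rownames(m) <- dense$gene
  if (nrow(cells) != ncol(m))
    stop("cells.csv has ", nrow(cells), " cells but matrix has ",
         ncol(m), " columns")
  colnames(m) <- cells$cell_id
  expr_matrix(m, cells)
}

#' Write / read a point pattern as CSV
#'
#' Columns: `cell_id, x_um, y_um, category, dapi, section_id, mouse_id,
#' region`; the window is stored in a small JSON sidecar next to the CSV.
#'
#' @param pattern a [point_pattern()].
#' @param path CSV file path.
#' @return `write_point_pattern` returns `path` invisibly;
#'   `read_point_pattern` returns a [point_pattern()].
#' @export
write_point_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  d <- pattern$cells
  out <- data.frame(cell_id = d$cell_id, x_um = d$x, y_um = d$y,
                    category = d$category, dapi = d$dapi_positive,
                    section_id = d$section_id, mouse_id = d$mouse_id,
                    region = d$region)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(window = pattern$window),
                       paste0(path, ".window.json"), digits = NA)
  invisible(path)
}

#' @rdname write_point_pattern
#' @param window optional `c(xmin, xmax, ymin, ymax)`; read from the
#'   sidecar when present, otherwise inferred from the data range.
#' @export
read_point_pattern <- function(path, window = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(window)) {
    side <- paste0(path, ".window.json")
    window <- if (file.exists(side)) {
      unlist(jsonlite::read_json(side)$window)
    } else c(min(d$x_um), max(d$x_um), min(d$y_um), max(d$y_um))
  }
  point_pattern(data.frame(cell_id = d$cell_id, x = d$x_um, y = d$y_um,
                           category = d$category, dapi_positive = d$dapi,
                           section_id = d$section_id, mouse_id = d$mouse_id,
                           region = if ("region" %in% names(d)) d$region else NA),
                window = window)
}
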