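# Synthetic per-cell QC tables with planted threshold violations.

#' Generate a synthetic Smart-seq2 QC table with planted violations
#'
#' Builds a per-cell QC metric table in which exactly the requested number
#' of cells violate each named metric; all remaining cells carry every
#' metric strictly inside its threshold interval. Violating cells are
#' disjoint across metrics, so the planted pass/fail ground truth is exact
#' and can serve as an oracle for the filter chain.
#'
#' Violations are placed on a uniformly drawn side of the interval that is
#' feasible within the metric's natural domain (e.g. a percentage bounded
#' above by 100 can only violate on the low side when its interval reaches
#' 100).
#'
#' @param n_cells number of cells (rows); 0 gives an empty table.
#' @param violations named list or vector, metric name -> number of cells
#'   that must fail that metric. Names must be among the nine Smart-seq2
#'   metrics; counts must sum to at most `n_cells`.
#' @param seed integer seed; fully determines the table.
#' @param thresholds [smartseq_thresholds()] object the violations are
#'   planted against.
#' @return `data.frame` with `cell_id`, the nine metric columns, and ground
#'   truth columns `qc_pass` (logical) and `violated_metric` (`NA` for
#'   passing cells).
#' @examples
#' tab <- generate_qc_table(100, list(reads = 5), seed = 1)
#' sum(!tab$qc_pass)
#' @export
generate_qc_table <- function(n_cells, violations = list(), seed = 1,
                              thresholds = smartseq_thresholds()) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 0)
  n_cells <- as.integer(n_cells)
  violations <- as.list(violations)
  if (length(violations)) {
    bad <- setdiff(names(violations), .smartseq_metrics)
    if (length(bad)) stop("unknown metric name(s): ", paste(bad, collapse = ", "))
    counts <- vapply(violations, function(x) as.integer(x), integer(1))
    if (any(counts < 0)) stop("violation counts must be non-negative")
    if (sum(counts) > n_cells)
      stop("violation counts (", sum(counts), ") exceed n_cells (", n_cells, ")")
  } else counts <- integer(0)

  empty <- data.frame(cell_id = character(0))
  for (m in .smartseq_metrics) empty[[m]] <- numeric(0)
  empty$qc_pass <- logical(0)
  empty$violated_metric <- character(0)
  if (n_cells == 0L) return(empty)

  with_seed(seed, {
    tab <- data.frame(cell_id = sprintf("cell_%05d", seq_len(n_cells)))
    # passing values: strictly inside, away from the bounds
    for (m in .smartseq_metrics) {
      b <- thresholds[[m]]
      w <- b[2] - b[1]
      tab[[m]] <- stats::runif(n_cells, b[1] + 0.05 * w, b[2] - 0.05 * w)
    }
    tab$reads <- round(tab$reads)
    tab$genes <- round(tab$genes)
    tab$qc_pass <- TRUE
    tab$violated_metric <- NA_character_

    perm <- sample.int(n_cells)
    used <- 0L
    for (m in names(violations)) {
      k <- as.integer(violations[[m]])
      if (k == 0L) next
      idx <- perm[(used + 1L):(used + k)]
      used <- used + k
      b <- thresholds[[m]]
      dom <- .smartseq_metric_domains[[m]]
      w <- max(b[2] - b[1], abs(b[2]) * 0.1, 1e-6)
      can_below <- b[1] > dom[1]
      can_above <- b[2] < dom[2]
      if (!can_below && !can_above)
        stop("metric '", m, "': interval covers its whole domain, cannot plant a violation")
      side <- if (can_below && can_above) {
        stats::runif(k) < 0.5
      } else rep(can_below, k)
      lo_vals <- stats::runif(k, max(dom[1], b[1] - 0.5 * w), b[1])
      hi_vals <- stats::runif(k, b[2], min(dom[2], b[2] + 0.5 * w))
      vals <- ifelse(side, lo_vals, hi_vals)
      if (m %in% c("reads", "genes"))
        vals <- ifelse(side, pmax(0, floor(lo_vals)), ceiling(hi_vals) + 1)
      tab[[m]][idx] <- vals
      tab$qc_pass[idx] <- FALSE
      tab$violated_metric[idx] <- m
    }
    tab
  })
}
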