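# Per-sample cell-state composition: proportions, boxplot summaries with
# the 1.5xIQR outlier convention, and a beta-binomial likelihood-ratio
# test of per-state compositional shifts between two groups with
# Benjamini-Hochberg FDR control.

#' Per-sample state counts from a cell-state assignment
#'
#' Tabulates cells by sample and state. `"unassigned"` is reported as its
#' own column when present. Sample-level metadata columns (one value per
#' sample) are carried through.
#'
#' @param assignment a [assign_states()] result, or any `data.frame` with
#'   `cell_id` and `state`.
#' @param metadata per-cell `data.frame` with `cell_id`, `sample_id` and
#'   optional sample-level columns (e.g. `group`, `age_months`,
#'   `tissue`).
#' @return A [composition_table()].
#' @export
proportions_per_sample <- function(assignment, metadata) {
  need <- c("cell_id", "sample_id")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(metadata$sample_id)) stop("cell(s) with missing sample_id")
  df <- merge(assignment[, c("cell_id", "state")], metadata, by = "cell_id")
  if (nrow(df) < nrow(assignment)) stop("cell(s) missing from metadata")
  tab <- table(df$sample_id, df$state)
  states <- colnames(tab)
  counts <- data.frame(sample_id = rownames(tab), as.data.frame.matrix(tab),
                       check.names = FALSE, stringsAsFactors = FALSE)
  # carry only metadata columns that are constant within each sample
  meta_cols <- setdiff(names(metadata), "cell_id")
  constant <- vapply(meta_cols, function(cl) {
    all(vapply(split(metadata[[cl]], metadata$sample_id),
               function(v) length(unique(v)) == 1L, logical(1)))
  }, logical(1))
  smeta <- unique(metadata[, meta_cols[constant], drop = FALSE])
  if ("sample_id" %in% names(smeta) && !anyDuplicated(smeta$sample_id))
    counts <- merge(smeta, counts, by = "sample_id", sort = FALSE)
  composition_table(counts, states = states)
}

#' Five-number boxplot summary with the 1.5xIQR outlier rule
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Whiskers extend to the most extreme data
#' points within 1.5xIQR of the box; anything beyond is an outlier.
#'
#' @param x numeric vector.
#' @return List with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @examples
#' boxplot_stats(c(1:9, 100))
#' @export
boxplot_stats <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
       outliers = sort(x[!inside]))
}

#' Boxplot summaries of state proportions per group
#'
#' @param table a [composition_table()].
#' @param group_col name of the grouping column in `table$counts`.
#' @return `data.frame` with one row per group x state: `median`, `q1`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
boxplot_summary <- function(table, group_col = "group") {
  stopifnot(inherits(table, "composition_table"))
  if (!group_col %in% names(table$counts)) stop("no column '", group_col, "'")
  pr <- composition_proportions(table)
  grp <- table$counts[[group_col]]
  rows <- list()
  for (g in unique(grp)) {
    for (s in table$states) {
      v <- pr[[s]][grp == g & !pr$empty]
      if (!length(v)) next
      b <- boxplot_stats(v)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, state = s, median = b$median, q1 = b$q1, q3 = b$q3,
        whisker_lo = b$whisker_lo, whisker_hi = b$whisker_hi,
        n_outliers = length(b$outliers), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Beta-binomial negative log-likelihood; mu in (0,1), theta > 0 is the
# concentration (a = mu*theta, b = (1-mu)*theta).
.bb_negll <- function(y, n, mu, theta) {
  a <- mu * theta
  b <- (1 - mu) * theta
  -sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

.bb_fit_null <- function(y, n) {
  p0 <- (sum(y) + 0.5) / (sum(n) + 1)
  fit <- stats::optim(
    c(stats::qlogis(p0), log(50)),
    function(par) {
      mu <- stats::plogis(par[1])
      theta <- exp(min(max(par[2], -5), 14))
      .bb_negll(y, n, mu, theta)
    })
  -fit$value
}

.bb_fit_alt <- function(y, n, g) {
  p1 <- (sum(y[g == levels(g)[1]]) + 0.5) / (sum(n[g == levels(g)[1]]) + 1)
  p2 <- (sum(y[g == levels(g)[2]]) + 0.5) / (sum(n[g == levels(g)[2]]) + 1)
  fit <- stats::optim(
    c(stats::qlogis(p1), stats::qlogis(p2), log(50)),
    function(par) {
      mu <- stats::plogis(par[1:2])
      theta <- exp(min(max(par[3], -5), 14))
      .bb_negll(y[g == levels(g)[1]], n[g == levels(g)[1]], mu[1], theta) +
        .bb_negll(y[g == levels(g)[2]], n[g == levels(g)[2]], mu[2], theta)
    })
  list(ll = -fit$value, effect = fit$par[2] - fit$par[1])
}

#' Test per-state compositional shifts between two groups
#'
#' For each state, the state-vs-rest counts per sample are modelled as
#' beta-binomial with a shared overdispersion and either one (null) or
#' two (alternative) group probabilities, both fitted by maximum
#' likelihood; the likelihood-ratio statistic is referred to chi-squared
#' with 1 df. The effect estimate is the fitted log-odds difference,
#' second group minus first with groups taken in order of appearance in
#' the table. P-values are Benjamini-Hochberg adjusted
#' across states and flagged at the configured FDR, whose default of 0.4
#' mirrors the permissive setting used for compositional screens of
#' subtle cell-state shifts.
#'
#' States absent from every sample are skipped with a note, as is the
#' degenerate case of a state comprising all cells of every sample.
#'
#' @param table a [composition_table()].
#' @param group_col grouping column in `table$counts`; must have exactly
#'   two levels with at least two samples each.
#' @param fdr FDR threshold for the `significant` flag (default 0.4).
#' @return `data.frame` of class `composition_test` with `state`,
#'   `effect_logodds`, `p`, `p_adjusted`, `significant`.
#' @export
test_composition <- function(table, group_col = "group", fdr = 0.4) {
  stopifnot(inherits(table, "composition_table"))
  if (!group_col %in% names(table$counts)) stop("no column '", group_col, "'")
  gv <- table$counts[[group_col]]
  g <- factor(gv, levels = unique(gv))  # order of appearance, not alphabetical
  if (nlevels(g) != 2L) stop("group factor must have exactly two levels")
  if (any(tabulate(g) < 2L)) stop("each group needs at least 2 samples")
  cm <- as.matrix(table$counts[, table$states, drop = FALSE])
  n <- rowSums(cm)
  rows <- list()
  for (s in table$states) {
    y <- cm[, s]
    if (sum(y) == 0) {
      message("test_composition: state '", s, "' absent from all samples; skipped")
      next
    }
    if (all(y == n)) {
      message("test_composition: state '", s, "' is 100% in all samples; skipped")
      next
    }
    ll0 <- .bb_fit_null(y, n)
    alt <- .bb_fit_alt(y, n, g)
    lr <- max(0, 2 * (alt$ll - ll0))
    rows[[length(rows) + 1L]] <- data.frame(
      state = s, effect_logodds = alt$effect,
      p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable state")
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p_adjusted <= fdr
  attr(out, "fdr") <- fdr
  attr(out, "groups") <- levels(g)
  class(out) <- c("composition_test", "data.frame")
  out
}
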