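# Dirichlet-multinomial simulation of per-sample cell-state compositions
# with a planted group effect on selected states.

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate a sample x state composition table
#'
#' Two groups of samples draw their state counts from a
#' Dirichlet-multinomial: expected proportions are `base_props` in the
#' reference group, and `base_props` with the named `effects` fold-changes
#' applied and re-normalised in the altered group. The concentration is
#' `1 / overdispersion`, so larger `overdispersion` spreads per-sample
#' proportions further around the group mean.
#'
#' @param base_props named numeric vector of state proportions summing
#'   to 1.
#' @param effects named numeric vector of fold-changes (> 0) applied to
#'   the altered group; empty for an exchangeable null.
#' @param n_samples_per_group samples per group (>= 1).
#' @param cells_per_sample cells drawn per sample.
#' @param overdispersion positive real; Dirichlet concentration is its
#'   reciprocal (default 0.02, concentration 50).
#' @param groups length-2 character vector of group labels.
#' @param seed integer seed.
#' @return List of class `composition_table`: `counts` (`data.frame` with
#'   `sample_id`, `group` and one column per state) and the planted
#'   ground-truth `effects`.
#' @examples
#' tab <- generate_composition_counts(
#'   c(Oligo1 = 0.8, IRO = 0.2), c(IRO = 3),
#'   n_samples_per_group = 3, cells_per_sample = 100, seed = 1)
#' tab$counts
#' @export
generate_composition_counts <- function(base_props, effects = c(),
                                        n_samples_per_group = 10,
                                        cells_per_sample = 1000,
                                        overdispersion = 0.02,
                                        groups = c("reference", "altered"),
                                        seed = 1) {
  if (is.null(names(base_props)) || abs(sum(base_props) - 1) > 1e-9)
    stop("base_props must be named and sum to 1")
  if (length(effects)) {
    bad <- setdiff(names(effects), names(base_props))
    if (length(bad)) stop("effects name unknown state(s): ", paste(bad, collapse = ", "))
    if (any(effects <= 0)) stop("effect folds must be > 0")
  }
  if (overdispersion <= 0) stop("overdispersion must be positive (degenerate concentration)")
  if (n_samples_per_group < 1) stop("each group needs at least one sample")
  conc <- 1 / overdispersion
  states <- names(base_props)
  alt_props <- base_props
  alt_props[names(effects)] <- alt_props[names(effects)] * effects
  alt_props <- alt_props / sum(alt_props)

  with_seed(seed, {
    rows <- list()
    for (g in 1:2) {
      pr <- if (g == 1) base_props else alt_props
      for (i in seq_len(n_samples_per_group)) {
        p <- .rdirichlet(conc * pr)
        cnt <- as.vector(stats::rmultinom(1, cells_per_sample, p))
        rows[[length(rows) + 1L]] <- c(list(
          sample_id = sprintf("%s_%02d", groups[g], i), group = groups[g]),
          stats::setNames(as.list(cnt), states))
      }
    }
    counts <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
    composition_table(counts, states = states,
                      effects = if (length(effects)) effects else NULL)
  })
}

#' Construct a composition-table container
#'
#' @param counts `data.frame` with `sample_id`, optional metadata columns,
#'   and one integer count column per state.
#' @param states character vector naming the state columns of `counts`.
#' @param effects optional planted ground-truth fold-changes.
#' @return List of class `composition_table`.
#' @export
composition_table <- function(counts, states, effects = NULL) {
  miss <- setdiff(c("sample_id", states), names(counts))
  if (length(miss)) stop("counts is missing column(s): ", paste(miss, collapse = ", "))
  cm <- as.matrix(counts[, states, drop = FALSE])
  if (any(cm < 0) || any(cm != round(cm))) stop("state counts must be non-negative integers")
  structure(list(counts = as.data.frame(counts), states = states,
                 effects = effects), class = "composition_table")
}

#' Per-sample state proportions of a composition table
#'
#' Rows with zero total cells get `NA` proportions and are flagged.
#'
#' @param table a [composition_table()].
#' @return `data.frame` of proportions with `sample_id` and a logical
#'   `empty` flag.
#' @export
composition_proportions <- function(table) {
  stopifnot(inherits(table, "composition_table"))
  cm <- as.matrix(table$counts[, table$states, drop = FALSE])
  tot <- rowSums(cm)
  pr <- sweep(cm, 1, ifelse(tot > 0, tot, NA_real_), "/")
  data.frame(sample_id = table$counts$sample_id, pr, empty = tot == 0,
             check.names = FALSE)
}
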