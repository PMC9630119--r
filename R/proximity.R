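# 20-micrometre proximity analysis between cell categories on imaged
# sections: observed neighbour fractions, a matched random-cell null
# drawn from DAPI+ nuclei, a paired t-test across mice, and the
# frontal-vs-medial subregional comparison.

#' Proximity analysis configuration
#'
#' @param radius neighbourhood radius in micrometres (default 20). A
#'   neighbour at exactly the radius counts (centre-to-centre distance,
#'   boundary inclusive).
#' @param aggregation how per-mouse fractions are formed: `"pool"`
#'   (default; pool all of a mouse's cells across its sections) or
#'   `"section_mean"` (mean of per-section fractions).
#' @param n_null_draws number of random-cell null draws (default 100; a
#'   single draw reproduces a one-shot manual random-cell selection).
#' @param exclude_subject whether the subject category is excluded from
#'   the random-cell pool in addition to the neighbour category
#'   (default TRUE).
#' @param method neighbour search backend: `"grid"` (bucketed spatial
#'   index) or `"brute"` (all-pairs distances). Both give identical
#'   results; `"brute"` exists as a built-in cross-check.
#' @param seed integer seed for the null draws.
#' @return List of class `proximity_config`.
#' @export
proximity_config <- function(radius = 20, aggregation = c("pool", "section_mean"),
                             n_null_draws = 100, exclude_subject = TRUE,
                             method = c("grid", "brute"), seed = 1) {
  if (radius <= 0) stop("radius must be > 0")
  if (n_null_draws < 1) stop("n_null_draws must be >= 1")
  structure(list(radius = radius, aggregation = match.arg(aggregation),
                 n_null_draws = as.integer(n_null_draws),
                 exclude_subject = isTRUE(exclude_subject),
                 method = match.arg(method), seed = as.integer(seed)),
            class = "proximity_config")
}

# Does each subject have >= 1 neighbour within radius (inclusive)?
# grid: neighbours bucketed into radius-sized cells, subjects check their
# 3x3 bucket neighbourhood. brute: all-pairs squared distances.
.has_neighbor <- function(sx, sy, nx, ny, radius, method = "grid") {
  ns <- length(sx)
  if (ns == 0L) return(logical(0))
  if (length(nx) == 0L) return(rep(FALSE, ns))
  r2 <- radius^2
  if (method == "brute") {
    return(vapply(seq_len(ns), function(i)
      any((nx - sx[i])^2 + (ny - sy[i])^2 <= r2), logical(1)))
  }
  bx <- floor(nx / radius); by <- floor(ny / radius)
  buckets <- split(seq_along(nx), paste(bx, by))
  vapply(seq_len(ns), function(i) {
    cx <- floor(sx[i] / radius); cy <- floor(sy[i] / radius)
    for (dx in -1:1) for (dy in -1:1) {
      idx <- buckets[[paste(cx + dx, cy + dy)]]
      if (!is.null(idx) &&
          any((nx[idx] - sx[i])^2 + (ny[idx] - sy[i])^2 <= r2)) return(TRUE)
    }
    FALSE
  }, logical(1))
}

.split_sections <- function(pattern) {
  cells <- pattern$cells
  lapply(split(cells, cells$section_id), function(d) d)
}

.aggregate_mouse <- function(per_cell, aggregation) {
  if (aggregation == "pool") {
    agg <- stats::aggregate(has_neighbor ~ mouse_id, per_cell, mean)
  } else {
    sec <- stats::aggregate(has_neighbor ~ mouse_id + section_id, per_cell, mean)
    agg <- stats::aggregate(has_neighbor ~ mouse_id, sec, mean)
  }
  names(agg)[2] <- "fraction"
  agg[order(agg$mouse_id), ]
}

#' Fraction of subject cells with a neighbour within the radius
#'
#' For every cell of `subject_category`, tests whether any cell of
#' `neighbor_category` in the same section lies at Euclidean
#' centre-to-centre distance at most `config$radius` (inclusive: a
#' neighbour at exactly 20.0 micrometres counts at the default radius).
#' Fractions are aggregated per mouse by pooling cells across the mouse's
#' sections (or by section means, see [proximity_config()]).
#'
#' @param pattern a [point_pattern()].
#' @param subject_category,neighbor_category category labels present in
#'   the pattern.
#' @param config a [proximity_config()].
#' @return List of class `proximity_fraction`: `per_mouse`
#'   (`mouse_id`, `fraction`), `per_cell` (per-subject flags),
#'   `n_subjects`, `n_neighbors`.
#' @export
fraction_with_neighbor <- function(pattern, subject_category, neighbor_category,
                                   config = proximity_config()) {
  stopifnot(inherits(pattern, "point_pattern"))
  cats <- unique(pattern$cells$category)
  if (!subject_category %in% cats) stop("unknown subject category: ", subject_category)
  # an absent neighbour category is legal: every fraction is then 0
  per_cell <- list()
  for (sec in .split_sections(pattern)) {
    sub <- sec[sec$category == subject_category, ]
    if (!nrow(sub)) next
    nb <- sec[sec$category == neighbor_category, ]
    flags <- .has_neighbor(sub$x, sub$y, nb$x, nb$y, config$radius, config$method)
    per_cell[[length(per_cell) + 1L]] <- data.frame(
      cell_id = sub$cell_id, mouse_id = sub$mouse_id,
      section_id = sub$section_id, has_neighbor = flags,
      stringsAsFactors = FALSE)
  }
  if (!length(per_cell)) stop("no subject cells in pattern")
  per_cell <- do.call(rbind, per_cell)
  structure(list(
    per_mouse = .aggregate_mouse(per_cell, config$aggregation),
    per_cell = per_cell,
    n_subjects = nrow(per_cell),
    n_neighbors = sum(pattern$cells$category == neighbor_category)
  ), class = "proximity_fraction")
}

#' Random-cell null for the proximity fraction
#'
#' Per draw and per section, a set of DAPI+ cells equal in size to the
#' section's `neighbor_category` count is sampled without replacement
#' (excluding cells of the neighbour category itself and, by default,
#' the subject category) and the subject-with-neighbour fraction is
#' recomputed with the sampled cells standing in as neighbours. Seeded
#' and reproducible.
#'
#' @inheritParams fraction_with_neighbor
#' @return List of class `proximity_null`: `draws` (n_null_draws x
#'   n_mice matrix of per-mouse null fractions), `per_mouse`
#'   (`mouse_id`, `null_fraction` = per-mouse mean over draws).
#' @export
random_cell_null <- function(pattern, subject_category, neighbor_category,
                             config = proximity_config()) {
  stopifnot(inherits(pattern, "point_pattern"))
  sections <- .split_sections(pattern)
  excl <- c(neighbor_category, if (config$exclude_subject) subject_category)
  prep <- lapply(sections, function(sec) {
    sub <- sec[sec$category == subject_category, ]
    pool <- sec[sec$dapi_positive & !(sec$category %in% excl), ]
    m <- sum(sec$category == neighbor_category)
    if (nrow(pool) < m)
      stop("section ", sec$section_id[1], ": eligible DAPI+ pool (", nrow(pool),
           ") smaller than matched neighbour count (", m, ")")
    # subject x pool within-radius adjacency, computed once; each draw is
    # then a cheap column subset instead of a fresh distance pass
    adj <- outer(sub$x, pool$x, "-")^2 + outer(sub$y, pool$y, "-")^2 <=
      config$radius^2
    list(sub = sub, pool = pool, m = m, adj = adj)
  })
  prep <- prep[vapply(prep, function(p) nrow(p$sub) > 0, logical(1))]
  if (!length(prep)) stop("no subject cells in pattern")

  with_seed(config$seed, {
    draw_list <- vector("list", config$n_null_draws)
    mouse_ids <- unlist(lapply(prep, function(p) p$sub$mouse_id))
    section_ids <- unlist(lapply(prep, function(p) p$sub$section_id))
    for (d in seq_len(config$n_null_draws)) {
      flags <- unlist(lapply(prep, function(p) {
        idx <- if (p$m > 0) sample.int(nrow(p$pool), p$m) else integer(0)
        if (length(idx)) rowSums(p$adj[, idx, drop = FALSE]) > 0
        else rep(FALSE, nrow(p$sub))
      }))
      draw_list[[d]] <- .aggregate_mouse(data.frame(
        mouse_id = mouse_ids, section_id = section_ids,
        has_neighbor = flags, stringsAsFactors = FALSE), config$aggregation)
    }
    mice <- draw_list[[1]]$mouse_id
    draws <- t(vapply(draw_list, function(a) a$fraction, numeric(length(mice))))
    draws <- matrix(draws, nrow = config$n_null_draws,
                    dimnames = list(NULL, mice))
    structure(list(
      draws = draws,
      per_mouse = data.frame(mouse_id = mice,
                             null_fraction = unname(colMeans(draws)),
                             stringsAsFactors = FALSE, row.names = NULL)
    ), class = "proximity_null")
  })
}

#' Paired t-test of observed versus null proximity fractions
#'
#' Classical paired Student's t-test on per-mouse differences
#' (observed minus null), two-sided. Degenerate zero-variance differences
#' yield `t = 0, p = 1` when all differences are zero, and `|t| = Inf,
#' p = 0` otherwise.
#'
#' @param observed,null numeric vectors of per-mouse fractions, paired
#'   and of equal length >= 2.
#' @return List of class `paired_test`: `t`, `df`, `p`, `differences`,
#'   `mean_difference`.
#' @export
paired_proximity_test <- function(observed, null) {
  if (length(observed) != length(null)) stop("paired vectors must have equal length")
  n <- length(observed)
  if (n < 2) stop("need >= 2 mice for a paired test")
  d <- observed - null
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t <- mean(d) / (sdd / sqrt(n))
  }
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  structure(list(t = t, df = n - 1, p = min(1, p), differences = d,
                 mean_difference = mean(d)), class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat("Paired t-test: t = ", signif(x$t, 4), ", df = ", x$df,
      ", p = ", signif(x$p, 4), "\n", sep = "")
  cat("mean difference:", signif(x$mean_difference, 4), "\n")
  invisible(x)
}

#' Observed-versus-null proximity analysis
#'
#' Convenience wrapper: observed per-mouse fractions, the matched
#' random-cell null, and the paired t-test of the two.
#'
#' @inheritParams fraction_with_neighbor
#' @return List of class `proximity_result`: `observed`
#'   ([fraction_with_neighbor()] result), `null` ([random_cell_null()]
#'   result), `test` ([paired_proximity_test()] result).
#' @export
proximity_analysis <- function(pattern, subject_category, neighbor_category,
                               config = proximity_config()) {
  obs <- fraction_with_neighbor(pattern, subject_category, neighbor_category, config)
  nul <- random_cell_null(pattern, subject_category, neighbor_category, config)
  if (!identical(obs$per_mouse$mouse_id, nul$per_mouse$mouse_id))
    stop("observed and null mice differ")
  structure(list(
    observed = obs, null = nul,
    test = paired_proximity_test(obs$per_mouse$fraction,
                                 nul$per_mouse$null_fraction)
  ), class = "proximity_result")
}

#' Compare a quantity between white-matter subregions across mice
#'
#' Sections are classified as frontal white matter (no lateral ventricles
#' in the section) or medial white matter (bordering the lateral
#' ventricles). Per mouse, section values are averaged within each
#' region, and region means are compared by a two-sided paired Student's
#' t-test across mice (difference: first region minus second).
#'
#' @param values `data.frame` with `mouse_id`, `region`, `value` (one row
#'   per section).
#' @param regions length-2 character vector of the regions to compare
#'   (default `frontal_WM` vs `medial_WM`).
#' @return List of class `subregional_result`: `per_mouse` (region means)
#'   and `test` (a `paired_test`).
#' @export
subregional_compare <- function(values, regions = c("frontal_WM", "medial_WM")) {
  miss <- setdiff(c("mouse_id", "region", "value"), names(values))
  if (length(miss)) stop("values is missing column(s): ", paste(miss, collapse = ", "))
  values <- values[values$region %in% regions, ]
  agg <- stats::aggregate(value ~ mouse_id + region, values, mean)
  wide <- stats::reshape(agg, idvar = "mouse_id", timevar = "region",
                         direction = "wide")
  cols <- paste0("value.", regions)
  miss_reg <- !stats::complete.cases(wide[, cols])
  if (any(miss_reg))
    stop("mouse missing a region: ", paste(wide$mouse_id[miss_reg], collapse = ", "))
  wide <- wide[order(wide$mouse_id), c("mouse_id", cols)]
  structure(list(
    per_mouse = stats::setNames(wide, c("mouse_id", regions)),
    test = paired_proximity_test(wide[[cols[1]]], wide[[cols[2]]])
  ), class = "subregional_result")
}
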