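# Parent-offspring simulation of imaged sections: uniform reference cells
# (CD8 T cells), target cells placed near a reference parent with a given
# association probability, over a homogeneous Poisson background of
# DAPI-positive nuclei.

#' Parameters for simulated tissue sections
#'
#' Defaults emulate a 600 x 600 micrometre white-matter field of view with
#' per-section counts scaled from a study quantifying 134 CD8+ T cells and
#' 272 interferon-responsive oligodendrocytes over 4 mice x 3 sections
#' (about 11 reference and 23 target cells per section), over roughly 360
#' background nuclei (intensity 1e-3 cells per square micrometre). No
#' field-of-view size was reported for the original sections, so the
#' window is an explicit, configurable choice.
#'
#' @param window_width,window_height window size in micrometres.
#' @param dapi_intensity background DAPI+ nuclei per square micrometre.
#' @param n_ref reference (CD8 T) cells per section.
#' @param n_target target (IRO/IRM) cells per section.
#' @param assoc_prob probability in `[0, 1]` that a target cell is placed
#'   near a uniformly chosen reference parent.
#' @param displacement_sigma isotropic Gaussian parent-offspring
#'   displacement scale in micrometres (> 0).
#' @param n_sections_per_mouse,n_mice study layout.
#' @param ref_category,target_category category labels carried by the
#'   generated cells.
#' @param region optional region label (`frontal_WM`, `medial_WM`, ...)
#'   stamped on every section.
#' @param seed integer seed.
#' @return List of class `spatial_sim_params`.
#' @export
spatial_sim_params <- function(window_width = 600, window_height = 600,
                               dapi_intensity = 1e-3, n_ref = 11,
                               n_target = 23, assoc_prob = 0,
                               displacement_sigma = 8,
                               n_sections_per_mouse = 3, n_mice = 4,
                               ref_category = "CD8_T",
                               target_category = "IRO",
                               region = NA_character_, seed = 1) {
  if (window_width <= 0 || window_height <= 0) stop("window dimensions must be > 0")
  if (assoc_prob < 0 || assoc_prob > 1) stop("assoc_prob must be in [0, 1]")
  if (displacement_sigma <= 0) stop("displacement_sigma must be > 0")
  exp_per_section <- dapi_intensity * window_width * window_height + n_ref + n_target
  if (exp_per_section * n_sections_per_mouse * n_mice > 1e6)
    stop("expected cell count exceeds 1e6; reduce intensity or window")
  structure(as.list(environment()), class = "spatial_sim_params")
}

#' Simulate sectioned point patterns with a planted spatial association
#'
#' Per section: background nuclei form a homogeneous Poisson process over
#' the window, reference cells are uniform, and each target cell is, with
#' probability `assoc_prob`, displaced from a uniformly chosen reference
#' parent by an isotropic Gaussian of scale `displacement_sigma`
#' (re-sampled until inside the window, avoiding edge pile-up), otherwise
#' uniform. Every cell is DAPI-positive, so the random-cell null can draw
#' from all nuclei.
#'
#' @param params a [spatial_sim_params()].
#' @return List of class `point_pattern`: `cells` (`cell_id`, `x`, `y`,
#'   `category`, `dapi_positive`, `section_id`, `mouse_id`, `region`),
#'   `window` (`c(0, width, 0, height)`), and the ground-truth
#'   `assoc_prob`.
#' @examples
#' pp <- generate_point_pattern(spatial_sim_params(n_mice = 1, seed = 3))
#' table(pp$cells$category)
#' @export
generate_point_pattern <- function(params = spatial_sim_params()) {
  stopifnot(inherits(params, "spatial_sim_params"))
  p <- params
  with_seed(p$seed, {
    out <- list()
    for (m in seq_len(p$n_mice)) {
      for (s in seq_len(p$n_sections_per_mouse)) {
        n_bg <- stats::rpois(1, p$dapi_intensity * p$window_width * p$window_height)
        runif_xy <- function(n) cbind(stats::runif(n, 0, p$window_width),
                                      stats::runif(n, 0, p$window_height))
        bg <- runif_xy(n_bg)
        ref <- runif_xy(p$n_ref)
        tgt <- runif_xy(p$n_target)
        clustered <- stats::runif(p$n_target) < p$assoc_prob
        for (i in which(clustered)) {
          parent <- ref[sample.int(p$n_ref, 1L), ]
          repeat {
            xy <- parent + stats::rnorm(2, 0, p$displacement_sigma)
            if (xy[1] >= 0 && xy[1] <= p$window_width &&
                xy[2] >= 0 && xy[2] <= p$window_height) break
          }
          tgt[i, ] <- xy
        }
        sec <- sprintf("m%02d_s%02d", m, s)
        xy <- rbind(bg, ref, tgt)
        cat_vec <- c(rep("DAPI_other", n_bg), rep(p$ref_category, p$n_ref),
                     rep(p$target_category, p$n_target))
        out[[length(out) + 1L]] <- data.frame(
          cell_id = sprintf("%s_c%04d", sec, seq_len(nrow(xy))),
          x = xy[, 1], y = xy[, 2], category = cat_vec,
          dapi_positive = TRUE, section_id = sec,
          mouse_id = sprintf("m%02d", m), region = p$region,
          stringsAsFactors = FALSE
        )
      }
    }
    point_pattern(do.call(rbind, out),
                  window = c(0, p$window_width, 0, p$window_height),
                  assoc_prob = p$assoc_prob)
  })
}

#' Construct a point-pattern container
#'
#' @param cells `data.frame` with at least `cell_id`, `x`, `y`,
#'   `category`, `dapi_positive`, `section_id`, `mouse_id`; an optional
#'   `region` column is added as `NA` when missing.
#' @param window numeric `c(xmin, xmax, ymin, ymax)` in micrometres.
#' @param assoc_prob optional planted ground-truth association.
#' @return List of class `point_pattern`.
#' @export
point_pattern <- function(cells, window, assoc_prob = NA_real_) {
  need <- c("cell_id", "x", "y", "category", "dapi_positive", "section_id", "mouse_id")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("point pattern is missing column(s): ", paste(miss, collapse = ", "))
  if (!"region" %in% names(cells)) cells$region <- NA_character_
  if (length(window) != 4L || window[2] <= window[1] || window[4] <= window[3])
    stop("window must be c(xmin, xmax, ymin, ymax)")
  if (any(cells$x < window[1] | cells$x > window[2] |
          cells$y < window[3] | cells$y > window[4]))
    stop("coordinates outside window")
  if (any(vapply(split(cells$cell_id, cells$section_id), anyDuplicated, integer(1)) > 0))
    stop("cell_ids must be unique within a section")
  if (any(!cells$dapi_positive & cells$category != "DAPI_other"))
    stop("categorised cells must be DAPI positive")
  structure(list(cells = as.data.frame(cells), window = as.numeric(window),
                 assoc_prob = assoc_prob), class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("<point_pattern> ", nrow(x$cells), " cells, ",
      length(unique(x$cells$section_id)), " sections, ",
      length(unique(x$cells$mouse_id)), " mice\n", sep = "")
  print(table(x$cells$category))
  invisible(x)
}
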