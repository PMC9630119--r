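# Wilcoxon rank-sum marker ranking with log2 fold-change filtering, and
# top-k marker overlaps between cell states.

# Two-sided rank-sum p for x vs y by exhaustive enumeration over all
# assignments of the observed (possibly tied) ranks to group A. Exact by
# construction, tie-safe; feasible for small groups.
.wilcox_exact_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w <- sum(r[seq_len(n1)])
  sums <- utils::combn(r, n1, sum)
  eps <- 1e-8
  min(1, 2 * min(mean(sums <= w + eps), mean(sums >= w - eps)))
}

# Normal approximation with tie correction and continuity correction.
.wilcox_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Rank marker genes between two cell groups
#'
#' Per gene: a two-sided Wilcoxon rank-sum test of normalised expression
#' in group A versus group B (exact enumeration when both groups have at
#' most `exact_max` cells, otherwise a normal approximation with tie and
#' continuity correction), and the average log2 fold-change
#' `log2((mean(expm1(A)) + eps) / (mean(expm1(B)) + eps))` with
#' `eps = 1e-9`. P-values are Benjamini-Hochberg adjusted across all
#' tested genes; when `fc_threshold` is set, rows with
#' `|avg_log2FC| <= fc_threshold` are then dropped (the conventional
#' `avg_log2FC > 1` marker cut).
#'
#' @param norm normalised genes x cells matrix ([normalize_log()] scale).
#' @param labels per-cell group labels aligned with `colnames(norm)`.
#' @param group_a,group_b labels of the two groups to contrast.
#' @param fc_threshold optional absolute log2 fold-change filter.
#' @param exact_max largest per-group size for the exact p-value path
#'   (default 10).
#' @return `data.frame` of class `marker_table` with `gene`,
#'   `avg_log2FC`, `p`, `p_adjusted`, `direction`, sorted by `p` then
#'   decreasing `|avg_log2FC|`. Groups with fewer than 2 cells yield an
#'   empty table with a warning.
#' @export
rank_markers <- function(norm, labels, group_a, group_b,
                         fc_threshold = NULL, exact_max = 10) {
  if (length(labels) != ncol(norm)) stop("labels must match columns of norm")
  ia <- which(labels == group_a)
  ib <- which(labels == group_b)
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  empty <- data.frame(gene = character(0), avg_log2FC = numeric(0),
                      p = numeric(0), p_adjusted = numeric(0),
                      direction = character(0))
  class(empty) <- c("marker_table", "data.frame")
  if (length(ia) < 2 || length(ib) < 2) {
    warning("a group has fewer than 2 cells; p undefined, all genes skipped")
    return(empty)
  }
  A <- as.matrix(norm[, ia, drop = FALSE])
  B <- as.matrix(norm[, ib, drop = FALSE])
  eps <- 1e-9
  lfc <- log2((rowMeans(expm1(A)) + eps) / (rowMeans(expm1(B)) + eps))
  exact <- length(ia) <= exact_max && length(ib) <= exact_max
  p <- vapply(seq_len(nrow(A)), function(g) {
    if (exact) .wilcox_exact_p(A[g, ], B[g, ]) else .wilcox_normal_p(A[g, ], B[g, ])
  }, numeric(1))
  out <- data.frame(gene = rownames(norm), avg_log2FC = lfc, p = p,
                    p_adjusted = stats::p.adjust(p, "BH"),
                    direction = ifelse(lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  if (!is.null(fc_threshold)) out <- out[abs(out$avg_log2FC) > fc_threshold, ]
  out <- out[order(out$p, -abs(out$avg_log2FC)), ]
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Overlap of the top-k markers of two tables
#'
#' Intersection of the top `k` genes of each [rank_markers()] table under
#' the table's documented sort (p then |log2FC|). Symmetric in its
#' arguments; tables shorter than `k` contribute all their rows (noted).
#'
#' @param markers_a,markers_b `marker_table` objects.
#' @param k number of top genes per table (default 50).
#' @return Character vector of shared genes.
#' @export
top_k_overlap <- function(markers_a, markers_b, k = 50) {
  take <- function(tab) {
    if (nrow(tab) < k)
      message("top_k_overlap: table has only ", nrow(tab), " rows (< k = ", k, "); using all")
    utils::head(tab$gene, k)
  }
  intersect(take(markers_a), take(markers_b))
}
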