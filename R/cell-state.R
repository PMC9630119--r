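# Log-normalisation, marker-signature scoring and threshold-based
# cell-state assignment. This stage stands where a full
# variance-stabilising transform + graph clustering pipeline would sit;
# the biology is carried by the marker sets, which are in scope.

#' Log-normalise a count matrix
#'
#' `log(1 + count / libsize * scale_factor)`, computed per cell with the
#' cell's total count as library size. Deterministic and sparse-preserving.
#'
#' @param x an [expr_matrix()] or genes x cells count matrix.
#' @param scale_factor positive scale (default 1e4).
#' @return Sparse genes x cells matrix of normalised expression.
#' @export
normalize_log <- function(x, scale_factor = 1e4) {
  counts <- if (inherits(x, "expr_matrix")) x$counts else
    methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  if (length(counts@x) && any(counts@x < 0)) stop("counts must be non-negative")
  lib <- Matrix::colSums(counts)
  if (any(lib == 0))
    stop("cell(s) with zero library size: ",
         paste(utils::head(colnames(counts)[lib == 0], 5), collapse = ", "),
         " -- run QC filtering first")
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / lib)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}

#' Marker gene signatures
#'
#' Construct a named signature set, or fetch the shipped defaults:
#' interferon-responsive oligodendrocytes (`IRO`: Stat1, Ifi27l2a, B2m,
#' H2-K1, H2-D1), age-related oligodendrocytes (`ARO`: Serpina3n, C4b),
#' interferon-responsive microglia (`IRM`: Stat1, Ifit3), the shared
#' interferon-stimulated set (`IFN_shared`: Stat1, Ifit3, Usp18,
#' Ifi27l2a) and T/NK cells (`T_NK`: Cd3d, Trbc2).
#'
#' @param name signature name.
#' @param genes non-empty character vector; duplicates removed.
#' @return `signature_set()` returns a list of class `signature_set`;
#'   `default_signatures()` a named list of them.
#' @export
signature_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("signature '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "signature_set")
}

#' @rdname signature_set
#' @export
default_signatures <- function() {
  list(
    IRO = signature_set("IRO", c("Stat1", "Ifi27l2a", "B2m", "H2-K1", "H2-D1")),
    ARO = signature_set("ARO", c("Serpina3n", "C4b")),
    IRM = signature_set("IRM", c("Stat1", "Ifit3")),
    IFN_shared = signature_set("IFN_shared", c("Stat1", "Ifit3", "Usp18", "Ifi27l2a")),
    T_NK = signature_set("T_NK", c("Cd3d", "Trbc2"))
  )
}

#' Build one signature per simulated state profile
#'
#' Convenience for recovery experiments: each [state_profile()] becomes a
#' [signature_set()] carrying its marker genes under the state's name.
#'
#' @param profiles list of [state_profile()] objects.
#' @return Named list of signatures.
#' @export
signatures_from_profiles <- function(profiles) {
  out <- lapply(profiles, function(p) signature_set(p$state, p$markers))
  stats::setNames(out, vapply(profiles, `[[`, character(1), "state"))
}

#' Score a marker signature per cell
#'
#' The score of a cell is the mean, over the signature's genes, of the
#' gene's across-cell z-score. Genes with zero variance contribute 0
#' (rather than NaN); genes absent from the matrix are dropped with a
#' note. Invariant to gene ordering.
#'
#' @param norm normalised genes x cells matrix (see [normalize_log()]).
#' @param sig a [signature_set()].
#' @return Named numeric vector of per-cell scores (z-units).
#' @export
score_signature <- function(norm, sig) {
  stopifnot(inherits(sig, "signature_set"))
  present <- intersect(sig$genes, rownames(norm))
  if (!length(present))
    stop("no gene of signature '", sig$name, "' present in the matrix")
  absent <- setdiff(sig$genes, present)
  if (length(absent))
    message("score_signature: '", sig$name, "' genes not in matrix: ",
            paste(absent, collapse = ", "))
  sub <- as.matrix(norm[present, , drop = FALSE])
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  z <- (sub - mu) / ifelse(sdv > 0, sdv, Inf)  # zero-variance rows -> 0
  stats::setNames(colMeans(z), colnames(norm))
}

#' Score several signatures at once
#'
#' @param norm normalised genes x cells matrix.
#' @param signatures named list of [signature_set()] objects.
#' @return Cells x signatures numeric matrix.
#' @export
score_signatures <- function(norm, signatures) {
  sc <- vapply(signatures, function(s) score_signature(norm, s),
               numeric(ncol(norm)))
  matrix(sc, nrow = ncol(norm),
         dimnames = list(colnames(norm),
                         vapply(signatures, `[[`, character(1), "name")))
}

#' Assign cell states from signature scores
#'
#' Each cell is labelled with the highest-scoring signature whose score
#' strictly exceeds its threshold; exact score ties are broken by rule
#' order (earlier rule wins). Cells with no signature above threshold are
#' labelled `"unassigned"`. The threshold is an analysis parameter of this
#' package (default 0.5 z-units), not a value inherited from any
#' clustering procedure.
#'
#' @param scores cells x signatures matrix from [score_signatures()].
#' @param rules `data.frame` with columns `signature` and `tau`
#'   (threshold), in priority order; or a character vector of signature
#'   names (all thresholds `tau`).
#' @param tau default threshold used when `rules` is a character vector.
#' @return `data.frame` of class `cell_state_assignment` with `cell_id`,
#'   `state`, and one score column per signature.
#' @export
assign_states <- function(scores, rules = colnames(scores), tau = 0.5) {
  if (is.character(rules)) rules <- data.frame(signature = rules, tau = tau)
  if (!nrow(rules)) stop("empty rule list")
  miss <- setdiff(rules$signature, colnames(scores))
  if (length(miss)) stop("rules reference unknown signature(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(rules$tau))) stop("thresholds must be finite")
  sc <- scores[, rules$signature, drop = FALSE]
  state <- rep("unassigned", nrow(sc))
  for (i in seq_len(nrow(sc))) {
    ok <- which(sc[i, ] > rules$tau)
    if (length(ok)) state[i] <- rules$signature[ok[which.max(sc[i, ok])]]
  }
  out <- data.frame(cell_id = rownames(scores), state = state,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores))
  class(out) <- c("cell_state_assignment", "data.frame")
  out
}
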