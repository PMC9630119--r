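# Gamma-Poisson simulation of gene x cell count matrices with planted
# cell states. The generator defines the study conditions used throughout
# the package's calibration and recovery experiments.

.mito_genes <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp6", "mt-Cytb")
.contaminant_genes <- c("Gm42418", "AY036118")

#' Describe a simulated study design
#'
#' A design is a set of samples (one sequencing run each) with animal,
#' age, genotype, tissue, platform and target cell number, plus the seed
#' that fully determines every downstream draw.
#'
#' @param samples `data.frame` with columns `sample_id`, `mouse_id`,
#'   `age_months` (3, 12, 18 or 24), `genotype` (`WT`, `RAG1KO`, `CD8KO`
#'   or `TREM2KO`), `tissue` (`GM`/`WM`), `platform`
#'   (`smartseq2`/`droplet`) and `n_cells` (>= 1).
#' @param seed integer seed.
#' @return List of class `sim_design`.
#' @export
sim_design <- function(samples, seed = 1) {
  need <- c("sample_id", "mouse_id", "age_months", "genotype", "tissue",
            "platform", "n_cells")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("design is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("sample_ids must be unique")
  if (!all(samples$age_months %in% c(3, 12, 18, 24)))
    stop("age_months must be one of 3, 12, 18, 24")
  if (!all(samples$genotype %in% c("WT", "RAG1KO", "CD8KO", "TREM2KO")))
    stop("unknown genotype")
  if (!all(samples$tissue %in% c("GM", "WM"))) stop("tissue must be GM or WM")
  if (!all(samples$platform %in% c("smartseq2", "droplet")))
    stop("platform must be smartseq2 or droplet")
  if (!all(samples$n_cells >= 1)) stop("n_cells must be >= 1")
  structure(list(samples = as.data.frame(samples), seed = as.integer(seed)),
            class = "sim_design")
}

#' Default eight-sample aged white-matter design
#'
#' Eight aged (24-month) wild-type white-matter samples (one mouse each),
#' mirroring the scale of a plate-based aging experiment at a
#' desk-friendly cell count. This is the condition the default state
#' profiles describe and the one used by the package's state-recovery
#' experiments.
#'
#' @param n_cells_per_sample cells per sample (default 250).
#' @param platform sequencing platform for all samples.
#' @param tissue tissue for all samples (default `"WM"`).
#' @param seed integer seed.
#' @return A [sim_design()].
#' @export
default_sim_design <- function(n_cells_per_sample = 250,
                               platform = "droplet", tissue = "WM",
                               seed = 1) {
  sim_design(data.frame(
    sample_id = sprintf("s%02d_%s", 1:8, tissue),
    mouse_id = sprintf("m%d", 1:8),
    age_months = 24,
    genotype = "WT",
    tissue = tissue,
    platform = platform,
    n_cells = n_cells_per_sample
  ), seed = seed)
}

#' Define a simulated cell state
#'
#' A state has a name, an expected proportion (scalar, or a named vector
#' keyed by `"<age>_<genotype>_<tissue>"` with an optional `"default"`
#' entry), a non-empty marker gene list, and a fold factor (>= 1) by which
#' marker means are elevated in cells of this state.
#'
#' @param state state name.
#' @param proportion scalar in `[0, 1]` or named condition-keyed vector.
#' @param markers character vector of marker genes.
#' @param fold multiplicative marker elevation, >= 1.
#' @return List of class `state_profile`.
#' @export
state_profile <- function(state, proportion, markers, fold = 8) {
  if (!length(markers)) stop("marker list must be non-empty")
  if (any(fold < 1)) stop("fold must be >= 1")
  if (any(proportion < 0 | proportion > 1)) stop("proportions must be in [0, 1]")
  structure(list(state = state, proportion = proportion,
                 markers = unique(as.character(markers)), fold = fold),
            class = "state_profile")
}

#' Default state profiles for the aged oligodendrocyte/T-cell mixture
#'
#' Four states with the marker sets observed in aged white matter:
#' baseline mature oligodendrocytes (`Oligo1`: a canonical myelin panel —
#' Plp1, Mal, Mog, Cldn11, Mbp, Mobp, Cnp, Ptgds), age-related
#' oligodendrocytes (`ARO`: Serpina3n, C4b), interferon-responsive
#' oligodendrocytes (`IRO`: Stat1, Ifi27l2a, B2m, H2-K1, H2-D1) and
#' T cells (`CD8_T`: Cd3d, Trbc2). Aged white matter carries a
#' substantial load of the aging-enriched states (proportions
#' 0.40/0.25/0.20/0.15); every other condition defaults to an
#' Oligo1-dominated composition (0.85/0.05/0.05/0.05).
#'
#' @param fold marker fold elevation applied to every state (default 8).
#' @return List of [state_profile()] objects.
#' @export
default_state_profiles <- function(fold = 8) {
  wm <- function(p_wm, p_gm) c("24_WT_WM" = p_wm, "default" = p_gm)
  list(
    state_profile("Oligo1", wm(0.40, 0.85),
                  c("Plp1", "Mal", "Mog", "Cldn11", "Mbp", "Mobp", "Cnp", "Ptgds"), fold),
    state_profile("ARO",    wm(0.25, 0.05), c("Serpina3n", "C4b"), fold),
    state_profile("IRO",    wm(0.20, 0.05), c("Stat1", "Ifi27l2a", "B2m", "H2-K1", "H2-D1"), fold),
    state_profile("CD8_T",  wm(0.15, 0.05), c("Cd3d", "Trbc2"), fold)
  )
}

.condition_key <- function(age, genotype, tissue) paste(age, genotype, tissue, sep = "_")

.profile_prop <- function(profile, key) {
  p <- profile$proportion
  if (is.null(names(p))) return(unname(p[1]))
  if (key %in% names(p)) return(unname(p[[key]]))
  if ("default" %in% names(p)) return(unname(p[["default"]]))
  stop("profile '", profile$state, "' has no proportion for condition ", key)
}

#' Simulate a gene x cell count matrix with planted states
#'
#' Counts follow a gamma-Poisson (negative binomial) model: per-gene base
#' means are drawn from a long-tailed lognormal, per-cell library-size
#' factors from a lognormal, and each cell's state multiplies that state's
#' marker means by the profile's fold factor. The gene universe always
#' contains the designated mitochondrial genes and the rRNA-contamination
#' indicator genes `Gm42418`/`AY036118`; ERCC spike-in features are added
#' for Smart-seq2 cells (zero in droplet cells). Ground-truth state labels
#' are attached to the cell metadata.
#'
#' @param design a [sim_design()].
#' @param profiles list of [state_profile()]; per condition the
#'   proportions must sum to 1 (tolerance 1e-9).
#' @param n_genes size of the endogenous gene universe (markers, mito and
#'   contaminant genes included; ERCC features are extra).
#' @param noise list of model knobs: `dispersion` (NB dispersion, 0 for
#'   pure Poisson; default 0.3), `libsize_sdlog` (lognormal sd of library
#'   factors, 0.3), `marker_base_mean` (base mean of marker genes, 2),
#'   `gene_mean_meanlog`/`gene_mean_sdlog` (lognormal base-mean
#'   parameters, log(0.3) and 1.2), `n_ercc` (spike-in features, 20).
#' @return List of class `expr_matrix` with `counts` (sparse dgCMatrix,
#'   genes x cells), `cells` (metadata with `true_state`) and `genes`.
#' @examples
#' x <- generate_counts(default_sim_design(50), n_genes = 120)
#' dim(x$counts)
#' @export
generate_counts <- function(design, profiles = default_state_profiles(),
                            n_genes = 500, noise = list()) {
  stopifnot(inherits(design, "sim_design"))
  nz <- list(dispersion = 0.3, libsize_sdlog = 0.3, marker_base_mean = 2,
             gene_mean_meanlog = log(0.3), gene_mean_sdlog = 1.2, n_ercc = 20)
  nz[names(noise)] <- noise

  states <- vapply(profiles, `[[`, character(1), "state")
  if (anyDuplicated(states)) stop("duplicate state names in profiles")
  markers <- lapply(profiles, `[[`, "markers")
  special <- unique(c(unlist(markers), .mito_genes, .contaminant_genes))
  n_fill <- n_genes - length(special)
  if (n_fill < 0)
    stop("n_genes too small: universe needs at least ", length(special), " genes")
  genes <- c(special, sprintf("gene%04d", seq_len(n_fill)))

  # per-condition proportion check
  keys <- unique(with(design$samples, .condition_key(age_months, genotype, tissue)))
  prop_tab <- sapply(keys, function(k) vapply(profiles, .profile_prop, numeric(1), key = k))
  prop_tab <- matrix(prop_tab, nrow = length(profiles),
                     dimnames = list(states, keys))
  bad <- abs(colSums(prop_tab) - 1) > 1e-9
  if (any(bad))
    stop("state proportions do not sum to 1 for condition(s): ",
         paste(keys[bad], collapse = ", "))

  with_seed(design$seed, {
    base_mean <- stats::rlnorm(length(genes), nz$gene_mean_meanlog, nz$gene_mean_sdlog)
    names(base_mean) <- genes
    base_mean[unique(unlist(markers))] <- nz$marker_base_mean
    base_mean[.mito_genes] <- 0.05
    base_mean[.contaminant_genes] <- 0.5

    smp <- design$samples
    cell_meta <- vector("list", nrow(smp))
    blocks <- vector("list", nrow(smp))
    for (i in seq_len(nrow(smp))) {
      n <- smp$n_cells[i]
      key <- .condition_key(smp$age_months[i], smp$genotype[i], smp$tissue[i])
      st <- sample(states, n, replace = TRUE, prob = prop_tab[, key])
      lib <- stats::rlnorm(n, 0, nz$libsize_sdlog)
      mu <- base_mean %o% lib
      for (j in seq_along(profiles)) {
        in_state <- st == states[j]
        if (any(in_state))
          mu[markers[[j]], in_state] <- mu[markers[[j]], in_state, drop = FALSE] * profiles[[j]]$fold
      }
      cnt <- if (nz$dispersion > 0) {
        matrix(stats::rnbinom(length(mu), size = 1 / nz$dispersion, mu = mu), nrow = nrow(mu))
      } else {
        matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
      }
      blocks[[i]] <- cnt
      cell_meta[[i]] <- data.frame(
        cell_id = sprintf("%s_c%04d", smp$sample_id[i], seq_len(n)),
        sample_id = smp$sample_id[i], mouse_id = smp$mouse_id[i],
        age_months = smp$age_months[i], genotype = smp$genotype[i],
        tissue = smp$tissue[i], platform = smp$platform[i],
        true_state = st, stringsAsFactors = FALSE
      )
    }
    counts <- do.call(cbind, blocks)
    cells <- do.call(rbind, cell_meta)

    if (nz$n_ercc > 0 && any(smp$platform == "smartseq2")) {
      ercc_names <- sprintf("ERCC-%05d", seq_len(nz$n_ercc))
      ercc_mu <- stats::rlnorm(nz$n_ercc, log(0.2), 1)
      is_ss2 <- cells$platform == "smartseq2"
      ercc <- matrix(0, nz$n_ercc, nrow(cells))
      if (any(is_ss2))
        ercc[, is_ss2] <- matrix(
          stats::rpois(nz$n_ercc * sum(is_ss2), rep(ercc_mu, sum(is_ss2))),
          nrow = nz$n_ercc)
      counts <- rbind(counts, ercc)
      genes <- c(genes, ercc_names)
    }

    dimnames(counts) <- list(genes, cells$cell_id)
    expr_matrix(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), cells)
  })
}

#' Construct an expression-matrix container
#'
#' @param counts genes x cells count matrix (coerced to sparse).
#' @param cells per-cell metadata `data.frame` with a `cell_id` column
#'   matching `colnames(counts)`.
#' @return List of class `expr_matrix`.
#' @export
expr_matrix <- function(counts, cells) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stop("counts must have gene rownames and cell colnames")
  if (!identical(colnames(counts), cells$cell_id))
    stop("cells$cell_id must match colnames(counts) in order")
  structure(list(counts = counts, cells = as.data.frame(cells),
                 genes = rownames(counts)), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells\n", sep = "")
  cat("  samples:", length(unique(x$cells$sample_id)),
      " platforms:", paste(unique(x$cells$platform), collapse = ","), "\n")
  invisible(x)
}
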