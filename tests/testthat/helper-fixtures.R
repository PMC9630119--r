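# Shared fixtures, built in code at test time.

# Tiny deterministic expression matrix with named genes.
toy_matrix <- function(n_genes = 50, n_cells = 20, seed = 1, extra_genes = NULL) {
  set.seed(seed)
  genes <- c(extra_genes, sprintf("g%03d", seq_len(n_genes - length(extra_genes))))
  m <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells,
              dimnames = list(genes, sprintf("c%03d", seq_len(n_cells))))
  expr_matrix(m, data.frame(cell_id = colnames(m)))
}

# Random point pattern with three categories in a rectangular window.
toy_pattern <- function(n_sub = 50, n_nb = 80, n_bg = 200, width = 500,
                        height = 500, n_mice = 2, seed = 1) {
  set.seed(seed)
  mk <- function(n, cat, mouse, sec) data.frame(
    x = runif(n, 0, width), y = runif(n, 0, height), category = cat,
    dapi_positive = TRUE, section_id = sec, mouse_id = mouse)
  rows <- list()
  for (m in seq_len(n_mice)) {
    sec <- sprintf("m%d_s1", m)
    rows[[m]] <- rbind(mk(n_sub, "IRO", sprintf("m%d", m), sec),
                       mk(n_nb, "CD8_T", sprintf("m%d", m), sec),
                       mk(n_bg, "DAPI_other", sprintf("m%d", m), sec))
  }
  cells <- do.call(rbind, rows)
  cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
  point_pattern(cells, window = c(0, width, 0, height))
}

# Independent brute-force QC predicate for oracle comparisons.
brute_smartseq_keep <- function(table, thresholds) {
  vapply(seq_len(nrow(table)), function(i) {
    all(vapply(names(thresholds), function(m) {
      v <- table[[m]][i]
      v >= thresholds[[m]][1] && v <= thresholds[[m]][2]
    }, logical(1)))
  }, logical(1))
}
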