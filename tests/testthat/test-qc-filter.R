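# Smart-seq2 and droplet filter chains against brute-force oracles and
# at every interval boundary.

test_that("smartseq bounds are inclusive at all 18 interval endpoints", {
  th <- smartseq_thresholds()
  base <- generate_qc_table(1, seed = 1)  # all metrics mid-interval
  for (m in names(th)) {
    for (side in 1:2) {
      cell <- base
      cell[[m]] <- th[[m]][side]
      res <- apply_smartseq_filters(cell, th)
      expect_equal(length(res$kept), 1,
                   label = sprintf("%s at %s bound kept", m, c("lower", "upper")[side]))
    }
  }
  # one past the boundary fails and is attributed to the right metric
  cell <- base
  cell$reads <- 19999
  res <- apply_smartseq_filters(cell, th)
  expect_equal(res$report$n_removed, 1)
  expect_equal(res$report$removed$failed_metrics, "reads")
})

test_that("smartseq filter equals brute-force predicate on random tables", {
  th <- smartseq_thresholds()
  tab <- generate_qc_table(1000, list(reads = 40, genes = 40, mean_read_length = 30,
                                      mismatch_rate = 30, pct_unique_mapped = 30,
                                      pct_multimapped = 30, pct_too_short = 20,
                                      frac_ercc = 20, frac_mito = 20), seed = 7)
  res <- apply_smartseq_filters(tab, th)
  keep <- brute_smartseq_keep(tab, th)
  expect_identical(res$kept, tab$cell_id[keep])
  expect_identical(sort(res$kept), sort(tab$cell_id[tab$qc_pass]))
  expect_equal(res$report$n_kept + res$report$n_removed, res$report$n_input)
})

test_that("smartseq filtering is idempotent and monotone in the intervals", {
  tab <- generate_qc_table(500, list(reads = 30, frac_mito = 30), seed = 3)
  res1 <- apply_smartseq_filters(tab)
  res2 <- apply_smartseq_filters(tab[tab$cell_id %in% res1$kept, ])
  expect_identical(res2$kept, res1$kept)
  expect_equal(res2$report$n_removed, 0)
  # widening an interval never shrinks the kept set
  wide <- smartseq_thresholds(reads = c(0, 1e9), frac_mito = c(0, 1))
  res_wide <- apply_smartseq_filters(tab, wide)
  expect_true(all(res1$kept %in% res_wide$kept))
})

test_that("smartseq filter rejects missing or non-numeric metric columns", {
  tab <- generate_qc_table(5, seed = 1)
  expect_error(apply_smartseq_filters(tab[, -2]), "missing column")
  tab$reads <- as.character(tab$reads)
  expect_error(apply_smartseq_filters(tab), "non-numeric")
})

test_that("droplet filters use strict bounds and the documented order", {
  set.seed(21)
  # gene g001 in only 2 cells -> removed by the gene filter first
  m <- matrix(rpois(40 * 30, 3), 40, 30,
              dimnames = list(c(sprintf("g%03d", 1:38), "mt-Nd1", "mt-Co1"),
                              sprintf("c%02d", 1:30)))
  m["g001", ] <- 0; m["g001", 1:2] <- 5
  x <- expr_matrix(m, data.frame(cell_id = colnames(m)))
  res <- apply_droplet_filters(x, droplet_params(min_genes_per_cell = 10,
                                                 max_frac_mito = 0.10,
                                                 max_umi = NULL, max_genes = NULL))
  expect_false("g001" %in% rownames(res$matrix$counts))
  expect_equal(unname(res$report$metric_failures["genes_removed"]), 1)

  # boundary behaviour: exactly min genes kept; exactly max mito kept
  m2 <- matrix(0, 300, 3, dimnames = list(c(sprintf("g%03d", 1:299), "mt-Nd1"),
                                          c("at_min", "below_min", "at_mito")))
  m2[1:200, "at_min"] <- 1                       # exactly 200 detected genes
  m2[1:199, "below_min"] <- 1                    # 199 genes
  m2[1:225, "at_mito"] <- 4                      # 900 counts
  m2["mt-Nd1", "at_mito"] <- 100                 # 100/1000 = 0.10 exactly
  x2 <- expr_matrix(m2, data.frame(cell_id = colnames(m2)))
  res2 <- apply_droplet_filters(x2, droplet_params(min_cells_per_gene = 0))
  expect_true(all(c("at_min", "at_mito") %in% colnames(res2$matrix$counts)))
  expect_false("below_min" %in% colnames(res2$matrix$counts))

  # strict UMI cap: a cell at exactly max_umi is removed
  m3 <- matrix(10, 20, 2, dimnames = list(sprintf("g%02d", 1:20), c("a", "b")))
  m3[, "b"] <- 5
  x3 <- expr_matrix(m3, data.frame(cell_id = colnames(m3)))
  res3 <- apply_droplet_filters(x3, droplet_params(min_cells_per_gene = 0,
                                                   min_genes_per_cell = 1,
                                                   max_umi = 200, max_genes = NULL))
  expect_identical(colnames(res3$matrix$counts), "b")
})

test_that("droplet filter equals a brute-force oracle on a random matrix", {
  set.seed(5)
  m <- matrix(rpois(500 * 300, 0.7), 500, 300,
              dimnames = list(c(sprintf("g%03d", 1:495), paste0("mt-", 1:5)),
                              sprintf("c%03d", 1:300)))
  x <- expr_matrix(m, data.frame(cell_id = colnames(m)))
  p <- droplet_params(min_cells_per_gene = 3, min_genes_per_cell = 150,
                      max_frac_mito = 0.02, max_umi = 400, max_genes = 250)
  res <- apply_droplet_filters(x, p)
  # oracle: same predicates, same order, dense arithmetic
  gk <- rowSums(m > 0) >= 3
  mg <- m[gk, ]
  det <- colSums(mg > 0)
  umi <- colSums(mg)
  fm <- colSums(mg[grepl("^mt-", rownames(mg)), ]) / pmax(umi, 1)
  keep <- det >= 150 & fm <= 0.02 & umi < 400 & det < 250
  expect_identical(colnames(res$matrix$counts), colnames(m)[keep])
  expect_identical(rownames(res$matrix$counts), rownames(m)[gk])
})

test_that("remove_genes drops named genes, ignores absent ones", {
  x <- toy_matrix(extra_genes = c("Gm42418", "AY036118"))
  out <- remove_genes(x)
  expect_false(any(c("Gm42418", "AY036118") %in% rownames(out$counts)))
  expect_equal(ncol(out$counts), ncol(x$counts))
  expect_identical(remove_genes(x, character(0)), x)
  expect_message(out2 <- remove_genes(x, c("Gm42418", "NotAGene")), "NotAGene")
  expect_equal(nrow(out2$counts), nrow(x$counts) - 1)
})
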