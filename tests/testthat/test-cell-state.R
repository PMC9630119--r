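# Normalisation, signature scoring, state assignment and marker ranking.

test_that("normalize_log matches the element-wise formula", {
  x <- toy_matrix(50, 20, seed = 2)
  norm <- normalize_log(x, scale_factor = 1e4)
  dense <- as.matrix(x$counts)
  lib <- colSums(dense)
  expected <- log1p(sweep(dense, 2, lib, "/") * 1e4)
  expect_equal(as.matrix(norm), expected, tolerance = 1e-12)
  # one-gene cell: value log(1 + scale_factor) regardless of the count
  one <- matrix(c(7, 3000), 1, 2, dimnames = list("g1", c("a", "b")))
  n1 <- normalize_log(expr_matrix(one, data.frame(cell_id = c("a", "b"))))
  expect_equal(as.numeric(n1), rep(log1p(1e4), 2))
})

test_that("normalize_log refuses zero-libsize cells", {
  m <- matrix(c(1, 2, 0, 0), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  x <- expr_matrix(m, data.frame(cell_id = c("a", "b")))
  expect_error(normalize_log(x), "zero library size")
})

test_that("signature scores equal hand-computed z-score means", {
  # 3 cells x 2 genes, computed by hand
  m <- matrix(c(0, 2, 4,
                1, 1, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  norm <- Matrix::Matrix(m, sparse = TRUE)
  sc <- score_signature(norm, signature_set("s", c("gA", "gB")))
  zA <- (m[1, ] - 2) / 2
  zB <- (m[2, ] - 2) / sqrt(3)
  expect_equal(unname(sc), unname((zA + zB) / 2))
})

test_that("signature scoring is order-invariant and zero-variance safe", {
  x <- toy_matrix(40, 15, seed = 3, extra_genes = c("Stat1", "Ifit3"))
  norm <- normalize_log(x)
  sig <- signature_set("IRM", c("Stat1", "Ifit3"))
  s1 <- score_signature(norm, sig)
  s2 <- score_signature(norm[rev(rownames(norm)), ], sig)
  expect_equal(s1, s2)
  # constant genes contribute 0
  m <- matrix(5, 2, 4, dimnames = list(c("gA", "gB"), sprintf("c%d", 1:4)))
  sc <- score_signature(Matrix::Matrix(m, sparse = TRUE),
                        signature_set("flat", c("gA", "gB")))
  expect_equal(unname(sc), rep(0, 4))
  expect_error(score_signature(norm, signature_set("none", "NotThere")),
               "no gene")
})

test_that("assign_states applies thresholds and rule-order tie-breaks", {
  sc <- matrix(c(0.2, 0.3,    # below tau -> unassigned
                 0.9, 0.9,    # exact tie -> earlier rule
                 0.6, 1.4),   # clear winner
               3, 2, byrow = TRUE,
               dimnames = list(c("u", "tie", "w"), c("IRO", "ARO")))
  asn <- assign_states(sc, rules = data.frame(signature = c("IRO", "ARO"), tau = 0.5))
  expect_equal(asn$state, c("unassigned", "IRO", "ARO"))
  expect_error(assign_states(sc, rules = data.frame(signature = character(0),
                                                    tau = numeric(0))), "empty rule")
  expect_error(assign_states(sc, rules = data.frame(signature = "IRO", tau = Inf)),
               "finite")
})

test_that("planted states are recovered at high marker fold", {
  x <- generate_counts(default_sim_design(250, seed = 1), n_genes = 300)
  sc <- score_signatures(normalize_log(x),
                         signatures_from_profiles(default_state_profiles()))
  asn <- assign_states(sc)
  expect_gt(mean(asn$state == x$cells$true_state), 0.95)
})

test_that("rank_markers agrees with closed-form exact rank-sum p-values", {
  # tie-free toys; independent oracle via the wilcoxon distribution
  set.seed(10)
  for (rep in 1:10) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    m <- matrix(rexp(3 * (n1 + n2)), 3,
                dimnames = list(c("g1", "g2", "g3"),
                                sprintf("c%02d", seq_len(n1 + n2))))
    labels <- rep(c("A", "B"), c(n1, n2))
    mk <- rank_markers(Matrix::Matrix(m, sparse = TRUE), labels, "A", "B")
    for (g in rownames(m)) {
      x <- m[g, labels == "A"]; y <- m[g, labels == "B"]
      u <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
      p_oracle <- min(1, 2 * min(pwilcox(u, n1, n2),
                                 1 - pwilcox(u - 1, n1, n2)))
      expect_equal(mk$p[mk$gene == g], p_oracle, tolerance = 1e-12)
    }
  }
})

test_that("identical groups give zero fold-change and p near 1", {
  m <- matrix(rep(c(1, 3, 0, 2), each = 8), 4, 8, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:8)))
  labels <- rep(c("A", "B"), 4)  # interleaved, groups identical
  mk <- rank_markers(Matrix::Matrix(m, sparse = TRUE), labels, "A", "B")
  expect_equal(mk$avg_log2FC, rep(0, 4))
  expect_true(all(mk$p > 0.9))
})

test_that("the fold-change threshold drops sub-threshold genes", {
  set.seed(4)
  base <- rnorm(30, 5, 0.05)
  m <- rbind(g_small = c(base[1:15] * 2^0.9, base[16:30]),  # ~0.9 log2FC
             g_big = c(base[1:15] * 8, base[16:30]))
  colnames(m) <- sprintf("c%02d", 1:30)
  labels <- rep(c("A", "B"), each = 15)
  norm <- Matrix::Matrix(log1p(m), sparse = TRUE)
  mk_all <- rank_markers(norm, labels, "A", "B")
  small_lfc <- mk_all$avg_log2FC[mk_all$gene == "g_small"]
  expect_gt(small_lfc, 0.5); expect_lt(small_lfc, 1)
  mk <- rank_markers(norm, labels, "A", "B", fc_threshold = 1)
  expect_false("g_small" %in% mk$gene)
  expect_true("g_big" %in% mk$gene)
})

test_that("BH adjustment is monotone and a tiny group is skipped", {
  x <- toy_matrix(60, 30, seed = 6)
  labels <- rep(c("A", "B"), 15)
  mk <- rank_markers(normalize_log(x), labels, "A", "B")
  expect_true(all(diff(mk$p_adjusted[order(mk$p)]) >= -1e-12))
  expect_true(all(mk$p_adjusted >= mk$p - 1e-12))
  expect_warning(
    empty <- rank_markers(normalize_log(x), c("A", rep("B", 29)), "A", "B"),
    "fewer than 2")
  expect_equal(nrow(empty), 0)
})

test_that("top_k_overlap is a symmetric top-k set intersection", {
  mk <- function(genes) {
    structure(data.frame(gene = genes,
                         avg_log2FC = seq_along(genes),
                         p = seq_along(genes) * 1e-4,
                         p_adjusted = seq_along(genes) * 1e-4,
                         direction = "up"),
              class = c("marker_table", "data.frame"))
  }
  a <- mk(sprintf("g%02d", 1:60)); b <- mk(sprintf("g%02d", c(1:30, 61:90)))
  expect_setequal(top_k_overlap(a, b, 50), sprintf("g%02d", 1:30))
  expect_setequal(top_k_overlap(b, a, 50), top_k_overlap(a, b, 50))
  expect_length(top_k_overlap(a, a, 50), 50)
  expect_length(top_k_overlap(a, mk(sprintf("x%02d", 1:60)), 50), 0)
  expect_message(top_k_overlap(mk(sprintf("g%02d", 1:10)), a, 50), "only 10")
})
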