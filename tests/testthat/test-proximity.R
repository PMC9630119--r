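# Neighbour fractions, the random-cell null, paired testing and the
# subregional comparison.

test_that("a neighbour at exactly the radius counts (inclusive boundary)", {
  cells <- data.frame(
    cell_id = c("s", "n", "far"),
    x = c(100, 120, 200), y = c(100, 100, 100),
    category = c("IRO", "CD8_T", "CD8_T"),
    dapi_positive = TRUE, section_id = "m1_s1", mouse_id = "m1")
  pp <- point_pattern(cells, c(0, 300, 0, 300))
  res <- fraction_with_neighbor(pp, "IRO", "CD8_T", proximity_config(radius = 20))
  expect_equal(res$per_mouse$fraction, 1)
  res19 <- fraction_with_neighbor(pp, "IRO", "CD8_T", proximity_config(radius = 19.999))
  expect_equal(res19$per_mouse$fraction, 0)
})

test_that("no neighbour cells gives fraction zero; categories validated", {
  cells <- data.frame(cell_id = c("a", "b"), x = c(10, 40), y = c(10, 40),
                      category = "IRO", dapi_positive = TRUE,
                      section_id = "m1_s1", mouse_id = "m1")
  pp <- point_pattern(cells, c(0, 100, 0, 100))
  res <- fraction_with_neighbor(pp, "IRO", "CD8_T", proximity_config())
  expect_equal(res$per_mouse$fraction, 0)
  expect_error(fraction_with_neighbor(pp, "XXX", "IRO", proximity_config()),
               "unknown subject")
})

test_that("grid-accelerated search equals all-pairs brute force", {
  for (s in 1:20) {
    pp <- toy_pattern(n_sub = 40, n_nb = 60, n_bg = 50, seed = s)
    g <- fraction_with_neighbor(pp, "IRO", "CD8_T",
                                proximity_config(method = "grid"))
    b <- fraction_with_neighbor(pp, "IRO", "CD8_T",
                                proximity_config(method = "brute"))
    expect_identical(g$per_cell$has_neighbor, b$per_cell$has_neighbor)
  }
})

test_that("observed fraction is non-decreasing in the radius", {
  pp <- toy_pattern(seed = 9)
  fr <- vapply(c(5, 10, 20, 40, 80), function(r)
    mean(fraction_with_neighbor(pp, "IRO", "CD8_T",
                                proximity_config(radius = r))$per_cell$has_neighbor),
    numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("random-cell null is seeded, reproducible and respects the pool", {
  pp <- toy_pattern(seed = 3)
  cfg <- proximity_config(n_null_draws = 20, seed = 11)
  n1 <- random_cell_null(pp, "IRO", "CD8_T", cfg)
  n2 <- random_cell_null(pp, "IRO", "CD8_T", cfg)
  expect_identical(n1$draws, n2$draws)
  n3 <- random_cell_null(pp, "IRO", "CD8_T", proximity_config(n_null_draws = 20, seed = 12))
  expect_false(identical(n1$draws, n3$draws))
  expect_true(all(n1$draws >= 0 & n1$draws <= 1))
  # pool too small: every DAPI cell is subject or neighbour
  cells <- data.frame(cell_id = c("a", "b"), x = c(1, 2), y = c(1, 2),
                      category = c("IRO", "CD8_T"), dapi_positive = TRUE,
                      section_id = "m1_s1", mouse_id = "m1")
  small <- point_pattern(cells, c(0, 10, 0, 10))
  expect_error(random_cell_null(small, "IRO", "CD8_T", cfg), "pool")
})

test_that("degenerate pool reproduces the observed fraction", {
  # all eligible random cells coincide with the true neighbour positions
  set.seed(8)
  n <- 15
  sub <- data.frame(x = runif(n, 0, 200), y = runif(n, 0, 200),
                    category = "IRO")
  nb <- data.frame(x = runif(n, 0, 200), y = runif(n, 0, 200),
                   category = "CD8_T")
  dup <- transform(nb, category = "DAPI_other")  # pool == neighbour positions
  cells <- rbind(sub, nb, dup)
  cells$cell_id <- sprintf("c%02d", seq_len(nrow(cells)))
  cells$dapi_positive <- TRUE; cells$section_id <- "m1_s1"; cells$mouse_id <- "m1"
  pp <- point_pattern(cells, c(0, 200, 0, 200))
  cfg <- proximity_config(n_null_draws = 5, seed = 2)
  obs <- fraction_with_neighbor(pp, "IRO", "CD8_T", cfg)
  nul <- random_cell_null(pp, "IRO", "CD8_T", cfg)
  expect_equal(nul$per_mouse$null_fraction, obs$per_mouse$fraction)
})

test_that("paired test matches the closed-form paired t and is antisymmetric", {
  obs <- c(0.50, 0.60, 0.55, 0.65)
  nul <- c(0.30, 0.35, 0.30, 0.40)
  res <- paired_proximity_test(obs, nul)
  d <- obs - nul
  t_hand <- mean(d) / (sd(d) / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3))
  # cross-check against the stock implementation
  ref <- t.test(obs, nul, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  swapped <- paired_proximity_test(nul, obs)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  # degenerate: identical vectors
  same <- paired_proximity_test(obs, obs)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
})

test_that("proximity_analysis detects a planted association", {
  pp <- generate_point_pattern(spatial_sim_params(assoc_prob = 0.5,
                                                  displacement_sigma = 8,
                                                  seed = 14))
  res <- proximity_analysis(pp, "IRO", "CD8_T",
                            proximity_config(n_null_draws = 50, seed = 15))
  expect_gt(res$test$mean_difference, 0.2)
  expect_lt(res$test$p, 0.01)
  expect_equal(res$test$df, 3)
})

test_that("subregional comparison averages sections then pairs mice", {
  vals <- data.frame(
    mouse_id = rep(c("m1", "m2", "m3"), each = 4),
    region = rep(rep(c("frontal_WM", "medial_WM"), each = 2), 3),
    value = c(1, 3, 5, 7,   2, 2, 8, 10,   3, 5, 6, 6))
  res <- subregional_compare(vals)
  frontal <- c(2, 2, 4); medial <- c(6, 9, 6)
  expect_equal(res$per_mouse$frontal_WM, frontal)
  expect_equal(res$per_mouse$medial_WM, medial)
  d <- frontal - medial
  expect_equal(res$test$t, mean(d) / (sd(d) / sqrt(3)))
  # identical regions -> p = 1
  same <- vals; same$value <- rep(c(1, 3), 6)
  expect_equal(subregional_compare(same)$test$p, 1)
  # a mouse missing one region is an error
  expect_error(subregional_compare(vals[vals$region == "medial_WM" |
                                          vals$mouse_id != "m2", ]),
               "missing a region")
})
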