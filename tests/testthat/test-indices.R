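test_that("geometric mean matches direct arithmetic on known scores", {
  # climate-style cell: six scores, sixth root of the product
  sc6 <- c(3.4, 8.0, 6.0, 6.0, 6.0, 5.0)
  idx <- geometric_mean_index(const_scores(sc6), "CQI")
  expect_equal(idx$grid$values[1, 1], prod(sc6)^(1 / 6))
  # soil-style cell: five scores
  sc5 <- c(2.5, 2.5, 1.7, 2.0, 2.0)
  idx5 <- geometric_mean_index(const_scores(sc5), "SQI")
  expect_equal(idx5$grid$values[1, 1], prod(sc5)^(1 / 5))
  # equal inputs are a fixed point (to double rounding)
  expect_equal(geometric_mean_index(const_scores(rep(10, 6)),
                                    "CQI")$grid$values,
               matrix(10, 2, 2))
})

test_that("geometric mean respects bounds, monotonicity and masks", {
  set.seed(10)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    vals <- runif(n, 0.5, 10)
    g <- geometric_mean_index(const_scores(vals), "CQI")$grid$values[1, 1]
    expect_gte(g, min(vals) - 1e-12)
    expect_lte(g, max(vals) + 1e-12)
    # raising one input never lowers the index
    vals2 <- vals
    i <- sample(n, 1)
    vals2[i] <- vals2[i] + runif(1, 0, 3)
    g2 <- geometric_mean_index(const_scores(vals2),
                               "CQI")$grid$values[1, 1]
    expect_gte(g2, g - 1e-12)
  }
  masked <- mk_grid(matrix(c(5, NA, 5, 5), 2, 2))
  out <- geometric_mean_index(list(masked, const_grid(5, 2, 2)), "CQI")
  expect_true(out$grid$mask[2, 1])
  expect_error(geometric_mean_index(list(const_grid(0, 2, 2)), "CQI"),
               "positivity")
})

test_that("index computation from a stack matches scored factors", {
  tb <- default_tables()
  # every soil factor in its bottom class
  st <- factor_stack(list(
    Sd = const_grid(5, 2, 2),           # < 10 -> 2.5
    St = const_grid(0.1, 2, 2),         # < 0.25 -> 2.5
    Sei = const_grid(1, 2, 2, levels = "Severe"),  # 1.7
    Som = const_grid(0.5, 2, 2),        # < 0.8 -> 2.0
    Sm = const_grid(0.04, 2, 2)))       # < 0.06 -> 2.0
  sqi <- compute_sqi(st, tb)
  expect_equal(sqi$grid$values[1, 1],
               (2.5 * 2.5 * 1.7 * 2.0 * 2.0)^(1 / 5))
  # all factors at their top class give index 10
  top <- factor_stack(list(
    Sd = const_grid(120, 2, 2), St = const_grid(0.9, 2, 2),
    Sei = const_grid(1, 2, 2, levels = "Slightly"),
    Som = const_grid(10, 2, 2), Sm = const_grid(0.15, 2, 2)))
  expect_true(all(abs(compute_sqi(top, tb)$grid$values - 10) < 1e-12))
  # missing factor is named
  expect_error(compute_cqi(st, tb), "Pr")
})

test_that("quality indices are permutation-invariant in their factors", {
  st <- small_scene(seed = 5, shape = c(12, 12))
  tb <- default_tables()
  cqi1 <- compute_cqi(st, tb)
  st_perm <- factor_stack(rev(unclass(st)))
  cqi2 <- compute_cqi(st_perm, tb)
  expect_equal(cqi1$grid$values, cqi2$grid$values)
})

test_that("EAI is the stated convex combination of the three indices", {
  five <- index_raster("CQI", const_grid(5, 2, 2))
  eai <- compute_eai(five, five, five)
  expect_true(all(eai$grid$values == 5))
  ten <- index_raster("CQI", const_grid(10, 2, 2))
  expect_equal(compute_eai(ten, five, five)$grid$values[1, 1],
               0.6 * 10 + 0.2 * 5 + 0.2 * 5)
  # degenerate weights reduce to CQI
  w <- index_weights(1, 0, 0)
  expect_equal(compute_eai(ten, five, five, w)$grid$values,
               ten$grid$values)
  # two-term printed form drops the soil term
  expect_equal(compute_eai(ten, five, five,
                           form = "two_term")$grid$values[1, 1],
               0.6 * 10 + 0.2 * 5)
  expect_error(index_weights(0.5, 0.2, 0.2), "sum to 1")
  expect_error(index_weights(-0.2, 1.0, 0.2), "non-negative")
})

test_that("EAI stays within the convex hull of its inputs cell-wise", {
  set.seed(11)
  for (rep in 1:100) {
    v <- runif(3, 1, 10)
    eai <- compute_eai(index_raster("CQI", const_grid(v[1])),
                       index_raster("SQI", const_grid(v[2])),
                       index_raster("VQI", const_grid(v[3])))$grid$values
    expect_gte(eai[1, 1], min(v) - 1e-12)
    expect_lte(eai[1, 1], max(v) + 1e-12)
  }
})

test_that("estimate_weights is seeded, reproducible and input-validated", {
  st <- small_scene(seed = 6, shape = c(30, 30))
  s <- suppressWarnings(generate_weight_training_samples(st, 400, seed = 2))
  w1 <- estimate_weights(s, n_trees = 30, mtry = 2, seed = 9)
  w2 <- estimate_weights(s, n_trees = 30, mtry = 2, seed = 9)
  expect_identical(w1$weights, w2$weights)
  expect_identical(w1$goodness, w2$goodness)
  expect_equal(sum(w1$weights), 1)
  expect_error(estimate_weights(s[1:50, ]), "at least 100")
  expect_error(estimate_weights(s, mtry = 4), "mtry")
  s_one <- s; s_one$label <- "PERA"
  expect_error(estimate_weights(s_one, n_trees = 5), "single class")
})

test_that("labels built from CQI alone concentrate importance on CQI", {
  st <- small_scene(seed = 12, shape = c(30, 30))
  s <- suppressWarnings(generate_weight_training_samples(st, 600, seed = 3))
  s$label <- ifelse(s$CQI > stats::median(s$CQI), "hi", "lo")
  wins <- 0L
  for (seed in 1:5) {
    w <- estimate_weights(s, n_trees = 40, mtry = 2, seed = seed)$weights
    if (which.max(w) == 1L) wins <- wins + 1L
  }
  expect_identical(wins, 5L)
})

test_that("labels independent of the indices give chance-level goodness", {
  st <- small_scene(seed = 13, shape = c(30, 30))
  s <- suppressWarnings(generate_weight_training_samples(st, 600, seed = 4))
  set.seed(99)
  s$label <- sample(c("a", "b"), nrow(s), replace = TRUE)
  g <- estimate_weights(s, n_trees = 60, mtry = 2, seed = 1)$goodness
  p0 <- max(table(s$label)) / nrow(s)   # majority-class chance level
  se <- sqrt(p0 * (1 - p0) / nrow(s))
  expect_lt(abs(g - p0), 3 * se + 0.02)
})
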