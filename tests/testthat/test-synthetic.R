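test_that("scene generation is a pure function of its seed", {
  s1 <- generate_base_scene(scene_spec(shape = c(25, 25), seed = 42))
  s2 <- generate_base_scene(scene_spec(shape = c(25, 25), seed = 42))
  for (f in names(s1)) expect_identical(s1[[f]]$values, s2[[f]]$values)
  s3 <- generate_base_scene(scene_spec(shape = c(25, 25), seed = 43))
  expect_false(identical(s1$Pr$values, s3$Pr$values))
  expect_error(scene_spec(band_shares = c(0.5, 0.2, 0.1, 0.1, 0.05)),
               "sum to 1")
})

test_that("the DEM realises the target elevation-band shares", {
  spec <- scene_spec(shape = c(200, 200), seed = 1)
  dem <- generate_base_scene(spec)$DEM$values
  shares <- tabulate(findInterval(dem, c(2300, 3600, 4400, 5000)) + 1L,
                     5L) / length(dem)
  expect_true(all(abs(shares - spec$band_shares) < 0.02))
  # highest ground sits in the northwest quadrant
  expect_gt(mean(dem[1:100, 1:100]), mean(dem[101:200, 101:200]))
})

test_that("quality factors rise from northwest to southeast", {
  st <- small_scene(seed = 8, shape = c(60, 60))
  nw <- function(m) mean(m[1:30, 1:30])
  se <- function(m) mean(m[31:60, 31:60])
  for (f in c("Pr", "T", "Di", "Par", "At", "Som", "NPP")) {
    expect_gt(se(st[[f]]$values), nw(st[[f]]$values), label = f)
  }
  # every categorical code is in its table's domain
  tb <- default_tables()
  expect_true(all(st$Sei$levels[st$Sei$values] %in%
                    names(tb$Sei$categories)))
  expect_true(all(st$Vrr$levels[st$Vrr$values] %in%
                    names(tb$Vrr$categories)))
  expect_true(all(st$A$levels[st$A$values] %in% names(tb$A$categories)))
})

test_that("noiseless scenario series recover the spec rate exactly", {
  st <- small_scene(seed = 9, shape = c(20, 20))
  spec <- scenario_spec("SSP585", pr_noise_sd = 0, t_noise_sd = 0,
                        n_members = 2, seed = 5)
  sim <- generate_scenario_series(st, spec)
  pr <- sim$series[sim$series$variable == "pr" &
                     sim$series$member == "member01", ]
  tr <- trend_rate(pr)
  expect_equal(tr$rate_per_decade, 16.6, tolerance = 1e-9)
  expect_equal(tr$r_squared, 1)
  tas <- sim$series[sim$series$variable == "tas" &
                      sim$series$member == "member01", ]
  expect_equal(trend_rate(tas)$rate_per_decade, 0.62, tolerance = 1e-9)
  expect_error(scenario_spec("SSP126", years = 2019:2100), "2021-2100")
  expect_error(scenario_spec("SSPX"), "unknown scenario")
})

test_that("noisy scenario trends recover the rate within OLS error", {
  st <- small_scene(seed = 10, shape = c(15, 15))
  years <- 2021:2100
  x <- years - mean(years)
  hits <- 0L
  for (seed in 1:20) {
    spec <- scenario_spec("SSP245", n_members = 1, seed = seed)
    sim <- generate_scenario_series(st, spec)
    pr <- sim$series[sim$series$variable == "pr", ]
    est <- trend_rate(pr)$rate_per_decade
    se_decade <- 10 * spec$pr_noise_sd / sqrt(sum(x^2))
    if (abs(est - 10.5) <= 3 * se_decade) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("the SE-wet / NW-warm pattern shapes per-cell trends", {
  st <- small_scene(seed = 11, shape = c(20, 20))
  spec <- scenario_spec("SSP370", pr_noise_sd = 0, t_noise_sd = 0,
                        spatial_rate_pattern = "pr_fast_SE_t_fast_NW",
                        n_members = 1, seed = 2)
  sim <- generate_scenario_series(st, spec)
  f0 <- sim$year_fields[["2021"]]; f1 <- sim$year_fields[["2100"]]
  pr_slope <- (f1$Pr$values - f0$Pr$values)
  t_slope <- (f1$T$values - f0$T$values)
  expect_gt(mean(pr_slope[11:20, 11:20]), mean(pr_slope[1:10, 1:10]))
  expect_gt(mean(t_slope[1:10, 1:10]), mean(t_slope[11:20, 11:20]))
  # static factors untouched by construction: only Pr and T are emitted
  expect_setequal(names(f0), c("Pr", "T"))
})

test_that("weight training samples are seeded and size-checked", {
  st <- small_scene(seed = 12, shape = c(20, 20))
  s1 <- suppressWarnings(generate_weight_training_samples(st, 150, seed = 3))
  s2 <- suppressWarnings(generate_weight_training_samples(st, 150, seed = 3))
  expect_identical(s1, s2)
  expect_error(suppressWarnings(
    generate_weight_training_samples(st, 1e6, seed = 1)), "exceeds")
  expect_true(all(s1$label %in% paper_schemes()$eai_risk$labels))
})

test_that("equal true weights never produce a dominant estimate", {
  st <- small_scene(seed = 14, shape = c(30, 30))
  s <- suppressWarnings(generate_weight_training_samples(
    st, 600, seed = 5, true_weights = c(1, 1, 1) / 3))
  for (seed in 1:5) {
    w <- estimate_weights(s, n_trees = 40, mtry = 2, seed = seed)$weights
    expect_lt(max(w), 0.5)
  }
})

test_that("end-to-end scene shows the published risk structure", {
  st <- small_scene(seed = 15, shape = c(60, 60))
  tb <- default_tables()
  eai <- compute_eai(compute_cqi(st, tb), compute_sqi(st, tb),
                     suppressWarnings(compute_vqi(st, tb)))
  risk <- classify_by_breaks(eai$grid, paper_schemes()$eai_risk)
  p <- class_proportions(risk)
  expect_true(all(p$percent > 0))        # all five classes present
  # risk decreases NW -> SE: the SE quadrant has the higher EAI
  v <- eai$grid$values
  expect_gt(mean(v[31:60, 31:60]), mean(v[1:30, 1:30]))
  # potential-risk (PERA) dominates the lowest elevation band
  bp <- band_proportions(risk, st$DEM)
  low <- bp[bp$stratum == "<2300", ]
  expect_identical(low$class[which.max(low$percent)], "PERA")
})
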