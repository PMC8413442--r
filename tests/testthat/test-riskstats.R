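risk_levels <- c("HeERA", "HERA", "LERA", "LeERA", "PERA")

test_that("class proportions are straight counting over unmasked cells", {
  codes <- matrix(3, 10, 10)           # LERA
  codes[1:4, 1:8] <- 2                 # 32 HERA cells
  g <- mk_grid(codes, levels = risk_levels)
  p <- class_proportions(g)
  expect_equal(p$percent[p$class == "HERA"], 32)
  expect_equal(p$percent[p$class == "LERA"], 68)
  expect_equal(sum(p$percent), 100)
  # masking half the cells renormalises over the rest
  m <- matrix(FALSE, 10, 10); m[, 1:5] <- TRUE
  g2 <- mk_grid(codes, mask = m, levels = risk_levels)
  p2 <- class_proportions(g2)
  expect_equal(sum(p2$percent), 100)
  expect_equal(p2$percent[p2$class == "HERA"],
               100 * sum(codes[, 6:10] == 2) / 50)
})

test_that("band proportions match hand counts on a crafted raster", {
  # 6x6: columns 1-2 low altitude, 3-4 mid, 5-6 high
  dem <- mk_grid(matrix(rep(c(2000, 2000, 4000, 4000, 5500, 5500),
                            each = 6), 6, 6))
  cls <- mk_grid(matrix(rep(c(5, 5, 3, 2, 1, 1), each = 6), 6, 6),
                 levels = risk_levels)
  bp <- band_proportions(cls, dem, elevation_bands())
  expect_identical(attr(bp, "empty_bands"), c("2300-3600", "4400-5000"))
  low <- bp[bp$stratum == "<2300", ]
  expect_equal(low$band_share[1], 100 * 12 / 36)
  expect_equal(low$percent[low$class == "PERA"], 100)
  mid <- bp[bp$stratum == "3600-4400", ]
  expect_equal(mid$percent[mid$class == "LERA"], 50)
  expect_equal(mid$percent[mid$class == "HERA"], 50)
  hi <- bp[bp$stratum == ">5000", ]
  expect_equal(hi$percent[hi$class == "HeERA"], 100)
  for (s in unique(bp$stratum))
    expect_equal(sum(bp$percent[bp$stratum == s]), 100, tolerance = 1e-9)
  expect_error(band_proportions(cls, mk_grid(matrix(0, 3, 3))), "aligned")
})

test_that("ensemble means average members year by year", {
  mk_series <- function(member, values) {
    data.frame(scenario = "SSP126", member = member, year = 2021:2023,
               variable = "pr", value = values, units = "mm")
  }
  em <- ensemble_mean(rbind(mk_series("a", c(1, 2, 3)),
                            mk_series("b", c(-1, -2, -3))))
  expect_equal(em$value, c(0, 0, 0))
  expect_identical(em$member, rep("ensemble", 3))
  # single member is the identity
  expect_equal(ensemble_mean(mk_series("a", c(5, 6, 7)))$value, c(5, 6, 7))
  # three constant members
  em3 <- ensemble_mean(rbind(mk_series("a", rep(1, 3)),
                             mk_series("b", rep(2, 3)),
                             mk_series("c", rep(3, 3))))
  expect_equal(em3$value, rep(2, 3))
  bad <- rbind(mk_series("a", 1:3),
               within(mk_series("b", 1:3), year <- year + 1))
  expect_error(ensemble_mean(bad), "year grids")
})

test_that("trend_rate matches closed-form OLS and the no-trend convention", {
  years <- 2021:2100
  exact <- data.frame(year = years, value = 0.062 * (years - 2021))
  tr <- trend_rate(exact)
  expect_equal(tr$rate_per_decade, 0.62)
  expect_equal(tr$r_squared, 1)
  # constant series
  tr0 <- trend_rate(data.frame(year = years, value = rep(3, 80)))
  expect_equal(tr0$rate_per_decade, 0)
  expect_equal(tr0$r_squared, 0)
  expect_error(trend_rate(data.frame(year = rep(2021, 5), value = 1:5)),
               "constant year")
  expect_error(trend_rate(data.frame(year = 2021:2022, value = 1:2)),
               "3 years")
  # closed form: 10 * sum((x-xbar)(y-ybar)) / sum((x-xbar)^2)
  set.seed(30)
  y <- rnorm(80)
  x <- years
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(trend_rate(data.frame(year = x, value = y))$rate_per_decade,
               10 * slope)
})

test_that("ensemble_mean commutes with trend_rate", {
  set.seed(31)
  years <- 2021:2060
  members <- lapply(1:4, function(m) {
    data.frame(scenario = "SSP245", member = paste0("m", m), year = years,
               variable = "tas", value = 0.03 * (years - 2021) + rnorm(40),
               units = "degC")
  })
  slope_of_mean <- trend_rate(ensemble_mean(members))$rate_per_decade
  mean_of_slopes <- mean(vapply(members, function(s)
    trend_rate(s)$rate_per_decade, numeric(1)))
  expect_equal(slope_of_mean, mean_of_slopes)
})

test_that("period means average cell-wise with mask union", {
  yrs <- as.character(2021:2040)
  grids <- setNames(lapply(2021:2040, function(y) const_grid(y - 2020, 2, 2)),
                    yrs)
  pm <- period_mean_stack(grids, "2021-2040")
  expect_true(all(pm$values == mean(1:20)))
  # identical rasters -> same raster; toy two-year mean
  toy <- list("2021" = const_grid(2, 2, 2), "2022" = const_grid(4, 2, 2))
  expect_true(all(period_mean_stack(toy, 2021:2022)$values == 3))
  # missing years are listed
  expect_error(period_mean_stack(grids[1:19], "2021-2040"), "2040")
  # a masked year masks the mean
  toy$`2022`$values[1, 1] <- NA; toy$`2022`$mask[1, 1] <- TRUE
  pm2 <- period_mean_stack(toy, 2021:2022)
  expect_true(pm2$mask[1, 1])
  expect_equal(pm2$values[2, 2], 3)
})

test_that("change rates difference proportion tables per stratum", {
  p1 <- data.frame(stratum = "all", class = risk_levels,
                   percent = c(10, 20, 30, 33, 7))
  expect_true(all(change_rates(p1, p1)$delta_pp == 0))
  # the published low-altitude PERA decline: 93.03 -> 90.51 is -2.52 points
  p_base <- data.frame(stratum = "<2300", class = risk_levels,
                       percent = c(0, 0.07, 1.72, 5.18, 93.03))
  p_fut <- data.frame(stratum = "<2300", class = risk_levels,
                      percent = c(0, 0.07, 1.72, 7.70, 90.51))
  ch <- change_rates(p_base, p_fut)
  expect_equal(ch$delta_pp[ch$class == "PERA"], -2.52)
  expect_equal(sum(ch$delta_pp), 0, tolerance = 1e-9)
  p_bad <- within(p1, class <- rev(risk_levels))
  expect_identical(sum(change_rates(p1, p_bad)$delta_pp), 0)
  p_missing <- p1[-1, ]
  expect_error(change_rates(p1, p_missing), "mismatched")
})
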