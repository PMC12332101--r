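briere2_remus <- function() published_params("te_remus", "briere2")

test_that("daily rate averages the min and max temperature rates", {
  p <- briere2_remus()
  expect_equal(daily_rate(p, 25, 25), evaluate_rate(p, 25))
  expect_equal(daily_rate(p, 20, 30),
               (evaluate_rate(p, 20) + evaluate_rate(p, 30)) / 2)
  expect_identical(daily_rate(p, 0, 5), 0)          # both below t_l
  expect_identical(daily_rate(p, 8.72, 35.04), 0)   # zero at both thresholds
  expect_error(daily_rate(p, 10, 5), "tmin must be <=")
})

test_that("constant-temperature generations equal 365 times the rate", {
  p <- briere2_remus()
  v <- annual_generations(constant_series(25), p)
  expect_equal(v$generations, 365 * evaluate_rate(p, 25), tolerance = 1e-12)
  expect_equal(v$generations, 29.5, tolerance = 0.01)
  cold <- annual_generations(constant_series(5), p)
  expect_identical(cold$generations, 0)
  expect_length(cold$completion_days, 0)
})

test_that("completions land where cumulative development reaches whole units", {
  # constant daily rate of exactly 0.1 via a Gaussian curve at its peak
  p <- model_params("taylor", c(rm = 0.1, t_opt = 25, t_sigma = 8))
  v <- annual_generations(constant_series(25), p)
  expect_equal(v$generations, 36.5, tolerance = 1e-9)
  expect_identical(v$completion_days[1:3], c(10L, 20L, 30L))
  expect_length(v$completion_days, 36L)
})

test_that("reset-with-carry accumulation equals the plain rate sum", {
  p <- briere2_remus()
  s <- sinusoid_series(mean = 20, amplitude = 8)
  v <- annual_generations(s, p)
  expect_equal(v$generations, sum(daily_rate(p, s$tmin, s$tmax)),
               tolerance = 1e-9)
})

test_that("total generations are rotation-invariant, completion days not", {
  p <- briere2_remus()
  s <- sinusoid_series(mean = 19, amplitude = 7)
  rot <- s[c(183:365, 1:182), ]
  rot$doy <- 1:365
  v1 <- annual_generations(s, p)
  v2 <- annual_generations(rot, p)
  expect_equal(v1$generations, v2$generations, tolerance = 1e-9)
  expect_false(identical(v1$completion_days, v2$completion_days))
})

test_that("incomplete years are rejected", {
  p <- briere2_remus()
  expect_error(annual_generations(constant_series(25)[-10, ], p),
               "365")
})

test_that("percentage difference matches the reported projection change", {
  expect_equal(round(percent_difference(8.27, 8.27 + 2.81), 2), 33.98)
  expect_identical(percent_difference(7, 7), 0)
  expect_identical(percent_difference(10, 5), -50)
  expect_warning(out <- percent_difference(0, 2), "undefined")
  expect_true(is.na(out))
  expect_error(percent_difference(-1, 2), ">= 0")
})

test_that("exceedance counting follows the boundary conventions", {
  th <- thermal_thresholds(t_l = 8.72, t_h = 35.04)
  inside <- constant_series(20)
  ex <- count_exceedance(inside, th)
  expect_identical(ex$days_below_tl, 0L)
  expect_identical(ex$days_above_th, 0L)
  crafted <- inside
  crafted$tmin[1:100] <- th$t_l - 1
  expect_identical(count_exceedance(crafted, th)$days_below_tl, 100L)
  # boundary: below uses strict <, above uses >=
  at_bounds <- constant_series(20)
  at_bounds$tmin[1:3] <- th$t_l
  at_bounds$tmax[1:5] <- th$t_h
  ex <- count_exceedance(at_bounds, th)
  expect_identical(ex$days_below_tl, 0L)
  expect_identical(ex$days_above_th, 5L)
  expect_error(count_exceedance(inside, thermal_thresholds()), "defined")
})

test_that("exceedance equals a day-by-day scan on a seasonal series", {
  th <- derive_thresholds(briere2_remus())
  s <- sinusoid_series(mean = 21, amplitude = 9, diurnal = 12)
  ex <- count_exceedance(s, th)
  below <- 0L
  above <- 0L
  for (i in 1:365) { # independent brute-force oracle
    if (s$tmin[i] < th$t_l) below <- below + 1L
    if (s$tmax[i] >= th$t_h) above <- above + 1L
  }
  expect_identical(ex$days_below_tl, below)
  expect_identical(ex$days_above_th, above)
  expect_gt(above, 0L)
  expect_gt(below, 0L)
})

test_that("uniform warming shifts exceedance monotonically", {
  th <- derive_thresholds(briere2_remus())
  s <- sinusoid_series(mean = 18, amplitude = 8)
  deltas <- c(0, 1, 2, 2.7, 4.4)
  counts <- lapply(deltas, function(d)
    count_exceedance(apply_delta(s, d), th))
  above <- vapply(counts, `[[`, integer(1), "days_above_th")
  below <- vapply(counts, `[[`, integer(1), "days_below_tl")
  expect_true(!is.unsorted(above))
  expect_true(!is.unsorted(rev(below)))
})

test_that("gridded voltinism matches per-cell computation and flags failures", {
  p <- briere2_remus()
  grid <- gen_climate_grid(n_cells = 6, mean_range = seq(12, 24, length.out = 6),
                           noise_sd = 0, seed = 5)
  th <- derive_thresholds(p)
  out <- voltinism_map(grid, p, scenario = "current", thresholds = th)
  expect_identical(nrow(out), 6L)
  # per-cell direct computation oracle
  for (cid in unique(grid$cell_id)) {
    v <- annual_generations(grid[grid$cell_id == cid, ], p)
    expect_equal(out$generations[out$cell_id == cid], v$generations)
  }
  # generations increase with the annual mean while means stay below t_opt
  expect_true(!is.unsorted(out$generations))
  # uniform grid gives identical cells
  uni <- gen_climate_grid(n_cells = 3, mean_range = rep(20, 3),
                          noise_sd = 0, seed = 6)
  res <- voltinism_map(uni, p)
  expect_equal(length(unique(round(res$generations, 9))), 1L)
  # a broken cell is reported, not dropped
  broken <- grid[!(grid$cell_id == "cell_001" & grid$doy == 200), ]
  expect_warning(res2 <- voltinism_map(broken, p), "failed")
  expect_false(res2$ok[res2$cell_id == "cell_001"])
  expect_true(all(res2$ok[res2$cell_id != "cell_001"]))
})

test_that("strong warming cuts voltinism in hot cells but boosts cold ones", {
  p <- briere2_remus()
  hot <- constant_series(31)
  hot$tmin <- 28
  hot$tmax <- 34 # already brushing the upper threshold
  cold <- constant_series(14)
  cold$tmin <- 10
  cold$tmax <- 18
  expect_lt(annual_generations(apply_delta(hot, 4.4), p)$generations,
            annual_generations(hot, p)$generations)
  expect_gt(annual_generations(apply_delta(cold, 4.4), p)$generations,
            annual_generations(cold, p)$generations)
})

test_that("a constant 25-degree cell yields about 29.5 generations", {
  p <- briere2_remus()
  grid <- rbind(constant_series(25, "warm"), constant_series(12, "cold"))
  out <- voltinism_map(grid, p)
  expect_equal(out$generations[out$cell_id == "warm"], 29.5,
               tolerance = 0.01)
})
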