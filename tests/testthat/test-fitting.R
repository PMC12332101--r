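test_that("linear fit equals the normal-equations solution", {
  d <- remus_fixture()
  f <- fit_linear(d)
  # closed-form OLS oracle
  x <- d$rates$temperature
  y <- d$rates$rate
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(f$params$values$b, b, tolerance = 1e-12)
  expect_equal(f$params$values$a, a, tolerance = 1e-12)
  expect_equal(f$thresholds$t_l, -a / b, tolerance = 1e-12)
  expect_equal(f$thresholds$k, 1 / b, tolerance = 1e-12)
})

test_that("linear fit recovers a noise-free line and flags degeneracy", {
  d <- development_dataset(c(15, 20, 25), 1 / (0.01 * (c(15, 20, 25) - 10)))
  f <- fit_linear(d)
  expect_equal(f$params$values$a, -0.1, tolerance = 1e-10)
  expect_equal(f$params$values$b, 0.01, tolerance = 1e-12)
  expect_equal(f$thresholds$t_l, 10, tolerance = 1e-8)
  expect_equal(f$thresholds$k, 100, tolerance = 1e-8)
  expect_lt(f$stats$sse, 1e-20)
  # two points: interpolating line, S undefined (n = k)
  d2 <- development_dataset(c(15, 25), c(50, 12))
  f2 <- fit_linear(d2)
  expect_true(is.na(f2$stats$s))
  expect_lt(f2$stats$sse, 1e-20)
  expect_error(development_dataset(20, 10), "at least 2")
})

test_that("fit statistics follow the least-squares conventions", {
  st <- fit_statistics(sse = 4e-4, n = 5, k = 2)
  expect_equal(st$s, sqrt(4e-4 / 3))
  expect_equal(st$aic, 5 * log(4e-4 / 5) + 2 * 3)
  expect_equal(st$bic, 5 * log(4e-4 / 5) + 3 * log(5))
  expect_true(is.na(fit_statistics(1e-4, n = 5, k = 5)$s))
})

test_that("delta criteria are invariant to an additive AIC constant", {
  sse <- c(2.8e-6, 1.2e-5, 3.6e-4)
  k <- c(4, 4, 2)
  aic1 <- 5 * log(sse / 5) + 2 * (k + 1)
  aic2 <- aic1 + 5 * log(2 * pi) + 5 # the full Gaussian log-likelihood form
  expect_equal(aic1 - min(aic1), aic2 - min(aic2), tolerance = 1e-12)
})

test_that("multi-start fitting recovers noise-free generating parameters", {
  true <- model_params("kontodimas",
                       c(alpha = 1.63e-5, t_l = 9.5, t_h = 46.79))
  d <- gen_dev_data(true, temperatures = seq(12, 44, length.out = 8),
                    cv = 0, seed = 3)
  f <- fit_nonlinear(d, "kontodimas", n_starts = 60, seed = 3)
  rel <- abs(unlist(f$params$values) - unlist(true$values)) /
    abs(unlist(true$values))
  expect_true(all(rel < 1e-4))
  expect_lt(f$stats$sse, 1e-12)
})

test_that("the returned fit is at least as good as every anchor start", {
  d <- remus_fixture()
  anchors <- list(c(a = 5e-5, t_l = 10, t_h = 38),
                  c(a = 2e-4, t_l = 5, t_h = 45))
  f <- fit_nonlinear(d, "briere1", n_starts = 25, anchors = anchors,
                     seed = 11)
  sse_at <- function(p) {
    pm <- model_params("briere1", p)
    v <- phenotherm:::rate_raw(pm, d$rates$temperature)
    v[!is.finite(v)] <- 0
    sum((v - d$rates$rate)^2)
  }
  for (a in anchors) expect_lte(f$stats$sse, sse_at(a) + 1e-12)
})

test_that("fitting errors are raised for unusable inputs", {
  d <- remus_fixture()
  expect_error(fit_nonlinear(d, "linear"), "fit_linear")
  expect_error(fit_nonlinear(d, "nonsense"), "unknown model")
  expect_error(
    fit_nonlinear(d, "briere1",
                  bounds = list(lower = c(a = 1e-7, t_l = -20, t_h = 30),
                                upper = c(a = Inf, t_l = 20, t_h = 50))),
    "finite")
})

test_that("noisy synthetic data recover the thresholds of four models", {
  # 25 seeded replicates per model with small Gaussian rate noise; at
  # least 80% of fits must place both thresholds within 1.5 degrees C
  for (m in c("briere1", "kontodimas", "performance2", "shi")) {
    true <- published_params("te_remus", m)
    th <- derive_thresholds(true)
    temps <- seq(th$t_l + 2, th$t_h - 0.5, length.out = 8)
    r_true <- evaluate_rate(true, temps)
    ok <- vapply(1:25, function(i) {
      set.seed(500 + i)
      r <- pmax(r_true + stats::rnorm(8, 0, 1e-3), 1e-4)
      d <- development_dataset(temps, 1 / r, species = "sim")
      f <- suppressWarnings(fit_nonlinear(d, m, n_starts = 40,
                                          seed = 500 + i))
      abs(f$params$values$t_l - th$t_l) < 1.5 &&
        abs(f$params$values$t_h - th$t_h) < 1.5
    }, logical(1))
    expect_gte(mean(ok), 0.8)
  }
})

test_that("plausibility marks follow the closed-range rule", {
  ranges <- plausibility_ranges()
  th <- thermal_thresholds(t_l = -17.89, t_opt = 32.96, t_h = 40.07)
  expect_identical(unname(screen_plausibility(th, ranges, "te_remus")),
                   c("-", "+", "-"))
  th <- thermal_thresholds(t_l = 11.16) # linear: t_opt/t_h not estimated
  expect_identical(unname(screen_plausibility(th, ranges, "te_remus")),
                   c("+", ".", "."))
  th <- thermal_thresholds(t_l = 8.72, t_opt = 34.00, t_h = 35.04)
  expect_identical(unname(screen_plausibility(th, ranges, "te_remus")),
                   c("+", "+", "+"))
  expect_error(screen_plausibility(th, ranges, "t_molestiae"),
               "no plausibility ranges")
})

test_that("model comparison computes deltas against the set minimum", {
  d <- remus_fixture()
  fits <- list(linear = fit_linear(d),
               briere1 = fit_nonlinear(d, "briere1", n_starts = 50,
                                       seed = 2))
  cmp <- compare_models(fits, species = "te_remus")
  expect_equal(min(cmp$delta_aic), 0)
  expect_equal(sum(cmp$delta_aic == 0), 1L)
  expect_true(all(cmp$delta_aic >= 0) && all(cmp$delta_bic >= 0))
  single <- compare_models(fits["linear"], species = "te_remus")
  expect_equal(single$delta_aic, 0)
  expect_equal(single$delta_bic, 0)
  expect_error(compare_models(list()), "no fits")
})

test_that("selection maximises plausible thresholds before fit quality", {
  mk <- function(model, n_plus, d_aic, k) {
    structure(data.frame(model = model, k = k, n_plausible = n_plus,
                         delta_aic = d_aic, stringsAsFactors = FALSE),
              class = c("model_comparison", "data.frame"))
  }
  two <- rbind(mk("worse_fit_all_plus", 3, 3.0, 4),
               mk("best_fit_one_minus", 2, 0.0, 4))
  class(two) <- c("model_comparison", "data.frame")
  expect_identical(select_best(two), "worse_fit_all_plus")
  # single candidate selects itself
  expect_identical(select_best(mk("only", 0, 0, 2)), "only")
  # invariant to input ordering
  rev2 <- two[2:1, ]
  class(rev2) <- c("model_comparison", "data.frame")
  expect_identical(select_best(rev2), "worse_fit_all_plus")
  # ties on marks and delta fall back to fewer parameters
  tie <- rbind(mk("complex", 2, 1.0, 5), mk("simple", 2, 1.0, 3))
  class(tie) <- c("model_comparison", "data.frame")
  expect_identical(select_best(tie), "simple")
})
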