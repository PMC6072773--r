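test_that("the Hill curve honours its defining points and monotonicity", {
  p <- list(a = 2.8, b = 4.4, c = 37.2)
  expect_identical(evaluate_hill(p, 0), 0)
  expect_equal(evaluate_hill(p, 37.2), 2.8 / 2)
  expect_equal(evaluate_hill(p, 1e9), 2.8, tolerance = 1e-6)
  x <- seq(0, 100, by = 0.5)
  expect_true(all(diff(evaluate_hill(p, x)) > 0))
})

test_that("noise-free synthetic data recover the generating parameters to 4 significant digits", {
  cfg <- synth_config(seed = 7, pain = list(a = 2, b = 5.7, c = 43.4,
                                            n = 50, sigma = 0,
                                            x_max = 100))
  pairs <- gen_pain_relief(cfg)
  fit <- fit_hill(pairs, n_boot = 0)
  truth <- attr(pairs, "truth")
  for (p in c("a", "b", "c"))
    expect_equal(fit$estimate[[p]], truth[[p]], tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.99999)
})

test_that("bootstrap intervals cover the truth on one noisy data set", {
  cfg <- synth_config(seed = 11)
  pairs <- gen_pain_relief(cfg)
  fit <- fit_hill(pairs, seed = 2, n_boot = 300)
  truth <- attr(pairs, "truth")
  for (p in c("a", "b", "c")) {
    expect_gte(fit$estimate[[p]], fit$ci[p, "lower"])
    expect_lte(fit$estimate[[p]], fit$ci[p, "upper"])
    expect_gte(truth[[p]], fit$ci[p, "lower"])
    expect_lte(truth[[p]], fit$ci[p, "upper"])
  }
})

test_that("degenerate inputs are refused instead of fitted", {
  flat <- data.frame(x = seq(0, 50, length.out = 10), y = rep(1.5, 10))
  expect_error(fit_hill(flat), "unidentifiable")
  same_x <- data.frame(x = rep(10, 10), y = rnorm(10))
  expect_error(fit_hill(same_x), "all equal|unidentifiable")
  expect_error(fit_hill(data.frame(x = 1:3, y = 1:3)), "at least 5")
  expect_error(fit_hill(data.frame(x = c(-1, 1:9), y = rnorm(10))),
               ">= 0")
})

test_that("fitting is invariant to the row order of the pairs", {
  cfg <- synth_config(seed = 3)
  pairs <- gen_pain_relief(cfg)
  f1 <- fit_hill(pairs, n_boot = 0)
  set.seed(42)
  f2 <- fit_hill(pairs[sample(nrow(pairs)), ], n_boot = 0)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-6)
})

test_that("bootstrap intervals shrink as the sample grows", {
  mk <- function(n, seed) gen_pain_relief(synth_config(
    seed = seed, pain = list(a = 2.8, b = 4.4, c = 37.2, n = n,
                             sigma = 0.14, x_max = 80)))
  f_small <- fit_hill(mk(20, 5), seed = 5, n_boot = 200)
  f_large <- fit_hill(mk(200, 5), seed = 5, n_boot = 200)
  w <- function(f) f$ci[, "upper"] - f$ci[, "lower"]
  expect_true(all(w(f_large) < w(f_small)))
})

test_that("model comparison prefers the generating model family", {
  # data from a steep Hill curve: Hill must beat the straight line
  hill_data <- gen_pain_relief(synth_config(
    seed = 21, pain = list(a = 2, b = 4, c = 40, n = 60, sigma = 0.1,
                           x_max = 80)))
  tab <- compare_models(hill_data)
  expect_identical(tab$model[1], "hill")
  expect_gt(tab$aic[tab$model == "linear"] -
              tab$aic[tab$model == "hill"], 2)
  # data from a line: the line must not lose to Hill by more than 2 AIC
  set.seed(31)
  x <- runif(60, 0, 80)
  line_data <- data.frame(x = x, y = 0.02 * x + rnorm(60, 0, 0.1))
  tab2 <- compare_models(line_data)
  expect_lte(tab2$aic[tab2$model == "linear"] -
               min(tab2$aic, na.rm = TRUE), 2)
  # a single candidate is trivially ranked first
  tab3 <- compare_models(hill_data, candidates = "hill")
  expect_identical(nrow(tab3), 1L)
  expect_identical(tab3$delta_aic, 0)
})
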