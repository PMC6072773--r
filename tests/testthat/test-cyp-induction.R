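test_that("zero rifampicin gives a flat activity fold of one", {
  prof <- data.frame(time = seq(0, 2880, by = 10), conc = 0)
  f <- simulate_induction(prof)
  expect_true(all(abs(f$fold[, "CYP3A4"] - 1) < 1e-9))
})

test_that("sustained saturating rifampicin drives the fold to Emax", {
  pars <- pxr_params(emax = 8, mrna_halflife_h = 2, enzyme_halflife_h = 6)
  prof <- data.frame(time = seq(0, 21 * 1440, by = 30), conc = 1e4)
  f <- simulate_induction(prof, pars)
  expect_equal(max(f$fold[, "CYP3A4"]), 8, tolerance = 0.01)
})

test_that("the cascade matches brute-force Euler integration for a step input", {
  pars <- pxr_params(emax = 5)
  step_conc <- function(t) ifelse(t >= 60, 10, 0)
  tt <- seq(0, 2880, by = 5)
  prof <- data.frame(time = tt, conc = step_conc(tt))
  f <- simulate_induction(prof, pars)
  h <- 0.05
  m <- 1; e <- 1
  euler <- numeric(length(tt)); euler[1] <- 1
  steps <- diff(range(tt)) / h
  k <- 2
  for (i in seq_len(steps)) {
    t <- (i - 1) * h
    stim <- 1 + (pars$emax - 1) * step_conc(t) / (pars$ec50 + step_conc(t))
    m <- m + h * pars$kdeg_mrna * (stim - m)
    e <- e + h * pars$kdeg_enzyme * (m - e)
    if (abs(i * h - tt[k]) < h / 2 && k <= length(tt)) {
      euler[k] <- e
      k <- k + 1
    }
  }
  rel <- max(abs(f$fold[, "CYP3A4"] - euler) / max(euler))
  expect_lt(rel, 0.005)
})

test_that("negative rifampicin concentrations are rejected", {
  expect_error(simulate_induction(data.frame(time = 0:2, conc = c(0, -1, 0))),
               "negative")
})

test_that("increment scaling reproduces its closed forms and orderings", {
  tt <- 0:10
  f3 <- activity_fold(tt, cbind(CYP3A4 = seq(1, 5, length.out = 11)))
  ext <- extend_to_other_cyps(f3, c(CYP2C9 = 0.18, CYP2J2 = 0.03,
                                    ZERO = 0, ONE = 1))
  expect_equal(unname(ext$fold[11, "CYP2C9"]), 1 + 0.18 * 4)  # fold3A4 = 5
  expect_true(all(abs(ext$fold[, "ZERO"] - 1) < 1e-12))
  expect_equal(ext$fold[, "ONE"], ext$fold[, "CYP3A4"])
  # monotone in ratio at every time; bounded by the CYP3A4 fold
  expect_true(all(ext$fold[, "CYP2J2"] <= ext$fold[, "CYP2C9"]))
  expect_true(all(ext$fold[, "CYP2C9"] <= ext$fold[, "CYP3A4"]))
  expect_error(extend_to_other_cyps(f3, c(CYP2C9 = 1.2)), "\\[0, 1\\]")
  expect_error(extend_to_other_cyps(f3, 0.5), "named")
})

test_that("folds decay back toward one after washout with the enzyme turnover half-life", {
  pars <- pxr_params(emax = 8, enzyme_halflife_h = 36)
  tt <- seq(0, 7 * 1440 + 6 * 1440, by = 30)
  conc <- ifelse(tt < 7 * 1440, 20, 0)   # one week on, then washout
  f <- simulate_induction(data.frame(time = tt, conc = conc), pars)
  i_end_rx <- max(which(f$time <= 7 * 1440))
  peak <- f$fold[i_end_rx, "CYP3A4"]
  i_72h <- max(which(f$time <= 7 * 1440 + 72 * 60))
  later <- f$fold[i_72h, "CYP3A4"]
  expect_lt(later, peak)
  # 72 h is two enzyme half-lives: excess fold should drop near 4-fold,
  # slowed a little by residual mRNA relaxation
  expect_lt((later - 1) / (peak - 1), 0.45)
  expect_gte(min(f$fold), 1)
})
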