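fake_profile <- function(time, pge2, wltb4) {
  structure(data.frame(time = time, PGE2 = pge2, wLTB4 = wltb4),
            class = c("mediator_profile", "data.frame"))
}

test_that("the drug efficacy score reproduces its defining arithmetic", {
  tt <- 0:2
  ctrl <- fake_profile(tt, rep(10, 3), rep(4, 3))
  expect_equal(compute_des(ctrl, ctrl, 1), 0)
  half_pge2 <- fake_profile(tt, rep(5, 3), rep(4, 3))
  expect_equal(compute_des(ctrl, half_pge2, 1), 0.25)
  half_both <- fake_profile(tt, rep(5, 3), rep(2, 3))
  expect_equal(compute_des(ctrl, half_both, 1), 0.5)
  full <- fake_profile(tt, rep(0, 3), rep(0, 3))
  expect_equal(compute_des(ctrl, full, 1), 1)
  # each fractional term is bounded by one, so DES <= 1
  expect_lte(compute_des(ctrl, full, 2), 1)
})

test_that("DES errors are explicit: grid mismatch and zero control mediator", {
  ctrl <- fake_profile(0:2, rep(10, 3), rep(4, 3))
  other <- fake_profile(c(0, 1, 3), rep(10, 3), rep(4, 3))
  expect_error(compute_des(ctrl, other, 1), "grid")
  zero_ctrl <- fake_profile(0:2, rep(0, 3), rep(4, 3))
  expect_error(compute_des(zero_ctrl, zero_ctrl, 1), "undefined")
})

test_that("the packaged registry holds the eleven therapeutic situations", {
  reg <- scenario_registry()
  expect_length(reg, 11)
  ids <- vapply(reg, function(s) s$id, numeric(1))
  expect_identical(sort(unname(ids)), as.numeric(1:11))
  drug_of <- function(i) vapply(reg[[as.character(i)]]$drugs,
                                function(d) d$drug, character(1))
  expect_identical(drug_of(1), "celecoxib")
  expect_identical(drug_of(2), "diclofenac")
  expect_identical(sort(drug_of(6)), c("celecoxib", "zileuton"))
  expect_identical(sort(drug_of(7)), c("diclofenac", "zileuton"))
  expect_identical(drug_of(5), "licofelone")
  # rifampicin arms carry a pre-treatment; efficacy arms do not
  has_pre <- vapply(reg, function(s) !is.null(s$pretreatment), logical(1))
  expect_identical(unname(has_pre[as.character(c(3, 4, 10, 11))]),
                   rep(TRUE, 4))
  expect_identical(unname(has_pre[as.character(c(1, 2, 5, 6, 7, 8, 9))]),
                   rep(FALSE, 7))
  # the two clinical DDI arms use the study regimens, not the generic one
  expect_equal(reg[["10"]]$pretreatment[c("dose_mg", "days")],
               list(dose_mg = 450, days = 6))
  expect_equal(reg[["11"]]$pretreatment[c("dose_mg", "days")],
               list(dose_mg = 600, days = 5))
  for (s in reg) expect_gte(length(load_drug(s$drugs[[1]]$drug)$targets$ki),
                            1)
})

test_that("a scenario whose drug binds with negligible affinity scores zero", {
  toy_yaml <- write_toy_drug_yaml(withr::local_tempfile(fileext = ".yaml"),
                                  ki = 1e9)
  sc <- make_scenario(99, "toy", list(list(
    drug = toy_yaml, dose_mg = 100, route = "oral",
    coupling_compartment = "central")), horizon_h = 2)
  res <- run_scenario(sc, phys = one_compartment_physiology())
  expect_lt(max(abs(res$des$des)), 1e-6)
})

test_that("control and treated runs differ only through the inhibitor signals", {
  sc <- load_scenario(2)
  res <- run_scenario(sc, dt = 2)
  expect_identical(res$control$time, res$treated$time)
  pre <- res$control$time <= 5   # before inhibition onset
  expect_equal(res$treated$PGE2[pre], res$control$PGE2[pre],
               tolerance = 1e-12)
  expect_lt(max(abs(res$des$des[res$des$time <= 5])), 1e-9)
  # DES at 0.5 h and horizon are read from the same trajectory
  expect_identical(res$des_at[["0.5h"]],
                   res$des$des[which.min(abs(res$des$time - 30))])
})

test_that("co-treatment with zileuton improves on each single agent early on", {
  r_cel <- run_scenario(load_scenario(1), dt = 2)
  r_combo <- run_scenario(load_scenario(6), dt = 2)
  expect_gte(r_combo$des_at[["0.5h"]], r_cel$des_at[["0.5h"]])
  expect_gte(r_combo$des_at[["horizon"]], r_cel$des_at[["horizon"]])
})

test_that("dose escalation is consistent at full dose and monotone on the surrogate", {
  sc <- load_scenario(1)
  tab <- dose_escalation(sc, fractions = c(1e-6, 0.1, 0.5, 1), dt = 2)
  expect_lt(tab$des_horizon[1], 1e-4)     # vanishing dose, vanishing effect
  full <- run_scenario(sc, dt = 2)
  expect_equal(tab$des_horizon[nrow(tab)], full$des_at[["horizon"]],
               tolerance = 1e-9)
  expect_true(all(diff(tab$des_horizon) >= -1e-9))
})

test_that("with the interaction disabled the dose-adjustment multiplier is one", {
  sc <- load_scenario(2)   # no pre-treatment: scenarios coincide
  res <- dose_adjustment_search(sc, sc, t_h = 1, dt = 2)
  expect_identical(res$multiplier, 1)
  expect_identical(res$multiplier_rounded, 1)
})

test_that("a clearance-doubling interaction on a linear toy drug needs twice the dose", {
  # toy one-compartment drug dosed to periodic steady state; inhibition far
  # below Ki makes the response linear in concentration, so doubling the
  # clearance must be compensated by doubling the dose
  toy_yaml <- write_toy_drug_yaml(withr::local_tempfile(fileext = ".yaml"),
                                  ki = 1e3, cl = 0.05)
  drugs <- list(list(drug = toy_yaml, dose_mg = 10, route = "oral",
                     repeat_interval = 60, repeat_count = 24,
                     coupling_compartment = "central"))
  sc_ref <- make_scenario(98, "toy-ref", drugs, horizon_h = 24)
  sc_ddi <- sc_ref
  folds_ddi <- c(CL = 2)
  res <- dose_adjustment_search(
    sc_ddi, sc_ref, t_h = 23, bracket = c(1, 4), tol_des = 1e-6,
    folds = folds_ddi, phys = one_compartment_physiology(), dt = 2)
  expect_equal(res$multiplier, 2, tolerance = 0.05)
  expect_identical(res$multiplier_rounded, 2)
})
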