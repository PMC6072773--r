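test_that("iv bolus into one compartment reproduces the mono-exponential closed form", {
  V <- 10; CL <- 0.1 / 60 * 10   # k = 0.1/h expressed as clearance
  model <- toy_model_cl(cl = CL, volume = V)
  prof <- simulate_pbpk(model, dose_event("intravenous", 100),
                        span = 72 * 60, dt = 1)
  c0 <- get_conc(prof, "toy", "central")$conc[1]
  expect_equal(c0, mg_to_umol(100, 300) / V, tolerance = 1e-8)
  m <- pk_metrics(prof, compartment = "central")
  # AUCinf = D / CL = 100 mg / (1 L/h) = 100 mg*h/L = 1e5 ng*h/ml
  expect_equal(m$auc_inf_ng_h_ml, 1e5, tolerance = 1e-3)
  expect_equal(m$tmax_h, 0, tolerance = 1e-8)
  # sampled profile matches C0 * exp(-k t)
  cc <- get_conc(prof, "toy", "central")
  expect_equal(cc$conc, c0 * exp(-0.1 / 60 * cc$time), tolerance = 1e-6)
})

test_that("large oral ka approaches the iv-bolus Cmax of the same dose", {
  iv <- simulate_pbpk(toy_model_cl(cl = 0.02), dose_event("intravenous", 50),
                      span = 24 * 60)
  fast <- simulate_pbpk(toy_model_cl(cl = 0.02, ka = 5),
                        dose_event("oral", 50), span = 24 * 60)
  cmax_iv <- pk_metrics(iv, compartment = "central")$cmax_ng_ml
  cmax_po <- pk_metrics(fast, compartment = "central")$cmax_ng_ml
  expect_gt(cmax_po / cmax_iv, 0.95)
  expect_lte(cmax_po / cmax_iv, 1)
})

test_that("mass balance holds below 1e-6 for every dosing pattern", {
  model <- toy_model_cl()
  for (doses in list(dose_event("intravenous", 100),
                     dose_event("oral", 100),
                     dose_event("oral", 50, time = 0,
                                repeat_interval = 240, repeat_count = 4))) {
    prof <- simulate_pbpk(model, doses, span = 24 * 60)
    expect_lt(mass_balance_error(prof), 1e-6)
  }
  # whole-body drug with metabolites
  dfn <- load_drug("diclofenac")
  prof <- simulate_pbpk(build_model(default_physiology(), dfn$spec),
                        dose_event("oral", 50), span = 12 * 60)
  expect_lt(mass_balance_error(prof), 1e-6)
})

test_that("a drug with zero processes under iv dosing conserves mass exactly", {
  phys <- one_compartment_physiology(volume = 8)
  drug <- drug_spec("inert", molecular_weight = 250, fraction_unbound = 0.5)
  prof <- simulate_pbpk(build_model(phys, drug),
                        dose_event("intravenous", 10), span = 600)
  expect_lt(mass_balance_error(prof), 1e-9)
  cc <- get_conc(prof, "inert", "central")
  expect_equal(diff(range(cc$conc)), 0, tolerance = 1e-9)
})

test_that("profiles scale linearly with dose under first-order kinetics", {
  dfn <- load_drug("diclofenac")
  model <- build_model(default_physiology(), dfn$spec)
  p1 <- simulate_pbpk(model, dose_event("oral", 25), span = 12 * 60)
  p2 <- simulate_pbpk(model, dose_event("oral", 50), span = 12 * 60)
  m1 <- pk_metrics(p1); m2 <- pk_metrics(p2)
  expect_equal(m2$cmax_ng_ml / m1$cmax_ng_ml, 2, tolerance = 1e-3)
  expect_equal(m2$auc_inf_ng_h_ml / m1$auc_inf_ng_h_ml, 2,
               tolerance = 1e-3)
  expect_equal(m2$tmax_h, m1$tmax_h, tolerance = 1e-6)
})

test_that("unbound concentration never exceeds total, with equality iff fu = 1", {
  dfn <- load_drug("diclofenac")
  prof <- simulate_pbpk(build_model(default_physiology(), dfn$spec),
                        dose_event("oral", 50), span = 6 * 60)
  df <- profile_df(prof)
  expect_true(all(df$unbound_umol_L <= df$total_umol_L + 1e-12))
  fu1 <- simulate_pbpk(toy_model_cl(fu = 1), dose_event("oral", 10),
                       span = 6 * 60)
  tot <- get_conc(fu1, "toy", "central", "total")$conc
  unb <- get_conc(fu1, "toy", "central", "unbound")$conc
  expect_identical(tot, unb)
})

test_that("metabolite chain bookkeeping: formed moles equal integrated parent flux", {
  m2 <- drug_spec("M2", 330, 0.2,
                  processes = list(adme_process("clearance_renal", "kidney",
                                                rate = 0.01)))
  m1 <- drug_spec("M1", 312, 0.1,
                  processes = list(
                    adme_process("metabolism", "liver_intracellular",
                                 enzyme = "CYP3A4", kcat = 20, km = 5,
                                 product = "M2")),
                  metabolites = list(m2))
  parent <- drug_spec("P", 296, 0.01,
                      absorption = list(ka = 0.05, lag = 0,
                                        formulation = "dissolved"),
                      processes = list(
                        adme_process("metabolism", "liver_intracellular",
                                     enzyme = "CYP2C9", kcat = 30, km = 5,
                                     product = "M1")),
                      metabolites = list(m1))
  model <- build_model(default_physiology(), parent)
  # state covers 3 compounds x all compartments
  expect_identical(dim(model$amt_idx), c(10L, 3L))
  expect_identical(colnames(model$amt_idx), c("P", "M1", "M2"))

  prof <- simulate_pbpk(model, dose_event("oral", 20), span = 24 * 60)
  expect_lt(mass_balance_error(prof), 1e-6)
  fd <- formed_df(prof)
  end <- fd[fd$time == max(fd$time), ]
  formed_m1 <- end$umol[grepl("^P\\.", end$process)]
  formed_m2 <- end$umol[grepl("^M1\\.", end$process)]
  # all M1 + M2 moles in the system plus eliminated M2 must equal the
  # parent moles metabolised (the flux accumulator)
  amounts <- prof$y[nrow(prof$y), ]
  in_m1 <- sum(amounts[grep("^M1\\|", names(amounts))])
  in_m2 <- sum(amounts[grep("^M2\\|", names(amounts))])
  elim_m2 <- amounts[["elim_renal|M2"]]
  expect_equal(in_m1 + formed_m2, formed_m1, tolerance = 1e-6)
  expect_equal(in_m2 + elim_m2, formed_m2, tolerance = 1e-6)
})

test_that("the packaged five-drug set implements 32 ADME processes", {
  drugs <- lapply(c("diclofenac", "celecoxib", "zileuton", "licofelone",
                    "rifampicin"), function(d) load_drug(d)$spec)
  expect_identical(do.call(n_adme_processes, drugs), 32)
})

test_that("unknown process sites and enzymes are rejected with the offender named", {
  phys <- default_physiology()
  bad_site <- drug_spec("x", 300, 0.5, processes = list(
    adme_process("clearance_renal", site = "spleen", rate = 0.01)))
  expect_error(build_model(phys, bad_site), "spleen")
  bad_enz <- drug_spec("x", 300, 0.5, processes = list(
    adme_process("metabolism", site = "liver_intracellular",
                 enzyme = "CYP9Z9", kcat = 1, km = 1)))
  expect_error(build_model(phys, bad_enz), "CYP9Z9")
})

test_that("drug spec validation enforces the documented invariants", {
  expect_error(drug_spec("x", -1, 0.5), "molecular_weight")
  expect_error(drug_spec("x", 300, 0), "fraction_unbound")
  expect_error(drug_spec("x", 300, 0.5,
                         absorption = list(ka = 0.1, formulation = "solid")),
               "dissolved")
  # cycle: drug that lists itself as metabolite
  expect_error({
    m <- drug_spec("x", 300, 0.5)
    m$metabolites <- list(m)
    validate_drug_spec(m)
  }, "cycle")
})

test_that("pk_metrics recovers the closed-form AUC of a mono-exponential decay", {
  V <- 10; k <- 0.005
  model <- toy_model_cl(cl = k * V, volume = V)
  prof <- simulate_pbpk(model, dose_event("intravenous", 10),
                        span = 2000, dt = 1)
  m <- pk_metrics(prof, compartment = "central")
  c0 <- umol_l_to_ng_ml(mg_to_umol(10, 300) / V, 300)
  expect_equal(m$auc_inf_ng_h_ml, c0 / (k * 60), tolerance = 1e-3)
  expect_true(m$extrapolated)
})

test_that("pk_metrics refuses terminal extrapolation for a non-decaying profile", {
  phys <- one_compartment_physiology(volume = 10)
  drug <- drug_spec("flat", molecular_weight = 300, fraction_unbound = 1)
  prof <- simulate_pbpk(build_model(phys, drug),
                        dose_event("intravenous", 10), span = 600)
  expect_warning(m <- pk_metrics(prof, compartment = "central"),
                 "terminal")
  expect_false(m$extrapolated)
})
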