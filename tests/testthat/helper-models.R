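# shared fixtures, all built in code

# one-compartment drug with a single first-order (renal) clearance
toy_drug_cl <- function(cl = 0.02, volume = 10, ka = 0.05, mw = 300,
                        fu = 1) {
  drug_spec("toy", molecular_weight = mw, fraction_unbound = fu,
            absorption = list(ka = ka, lag = 0, formulation = "dissolved"),
            processes = list(
              adme_process("clearance_renal", site = "central",
                           rate = cl / volume)))
}

toy_model_cl <- function(cl = 0.02, volume = 10, ka = 0.05, fu = 1) {
  build_model(one_compartment_physiology(volume = volume),
              toy_drug_cl(cl = cl, volume = volume, ka = ka, fu = fu))
}

# one-compartment drug cleared only by an enzyme-mediated (inducible)
# metabolism process operating far below Km, i.e. linear with slope
# kcat/km = cl (in L/min)
toy_drug_enzyme <- function(cl = 0.02, km = 1e4) {
  drug_spec("toy", molecular_weight = 300, fraction_unbound = 1,
            absorption = list(ka = 0.05, lag = 0,
                              formulation = "dissolved"),
            processes = list(
              adme_process("metabolism", site = "central", enzyme = "CL",
                           kcat = cl * km, enzyme_scale = 1, km = km,
                           product = NULL)))
}

toy_model_enzyme <- function(cl = 0.02, volume = 10) {
  build_model(one_compartment_physiology(volume = volume),
              toy_drug_enzyme(cl = cl))
}

# constant-concentration inhibitor signal without onset delay
const_signal <- function(conc, enzyme = "COX-2", ki = 1,
                         onset_delay = 0) {
  inhibitor_signal("probe", enzyme, ki, function(t) rep(conc, length(t)),
                   t_dose = 0, onset_delay = onset_delay)
}

# scenario object assembled in code (bypasses the YAML registry)
make_scenario <- function(id, label, drugs, pretreatment = NULL,
                          horizon_h = 6) {
  structure(list(id = id, label = label, drugs = drugs,
                 pretreatment = pretreatment, horizon_h = horizon_h,
                 result = "drug_efficacy"),
            class = "scenario")
}

# write a minimal one-compartment drug YAML with a declared target;
# returns the file path (for scenario-level tests with custom drugs)
write_toy_drug_yaml <- function(path, ki = 1e9, cl = 0.02) {
  cfg <- list(
    name = "toy", abbreviation = "TOY", therapeutic_dose_mg = 100,
    molecular_weight = 300, fraction_unbound = 1,
    targets = list(list(enzyme = "COX-2", ki = ki)),
    absorption = list(ka = 0.05, lag = 0, formulation = "dissolved"),
    processes = list(list(kind = "metabolism", site = "central",
                          enzyme = "CL", kcat = cl * 1e4, km = 1e4)))
  yaml::write_yaml(cfg, path)
  path
}
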