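#' Seeded synthetic-data generators
#'
#' Every stage of the pipeline can be exercised without external data:
#' noisy oral-dose plasma observations (proportional log-normal residual
#' error, the standard model for concentration data), pain-relief scores
#' from a Hill curve plus additive Gaussian noise, and toy inhibition
#' networks with algebraically known steady states.  All generators are
#' pure functions of their configuration: a fixed seed gives byte-identical
#' output.
#'
#' @param seed integer RNG seed.
#' @param pk list: `dose_mg`, `volume` (L), `cl` (L/min), `ka` (1/min),
#'   `times` (sampling times, min), `cv` (log-normal coefficient of
#'   variation), `mw` (g/mol).
#' @param pain list: `a`, `b`, `c` (true Hill parameters), `n`, `sigma`
#'   (additive noise SD), `x_max` (range of PGE2 decrease sampled).
#' @param network list: `id` (toy network identifier; `"linear_chain"`).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         pk = list(dose_mg = 100, volume = 10,
                                   cl = 0.02, ka = 0.02,
                                   times = c(15, 30, 45, 60, 90, 120, 180,
                                             240, 360, 480, 720, 1440),
                                   cv = 0.1, mw = 300),
                         pain = list(a = 2.8, b = 4.4, c = 37.2, n = 50,
                                     sigma = 0.14, x_max = 80),
                         network = list(id = "linear_chain")) {
  stopifnot(pk$cv >= 0, pain$sigma >= 0, pain$n >= 1)
  structure(list(seed = as.integer(seed), pk = pk, pain = pain,
                 network = network),
            class = "synth_config")
}

# the shared toy PK model: one-compartment, oral absorption, linear
# clearance expressed as a renal clearance process.  internal
toy_pk_model <- function(pk) {
  phys <- one_compartment_physiology(volume = pk$volume)
  drug <- drug_spec("toy", molecular_weight = pk$mw, fraction_unbound = 1,
                    absorption = list(ka = pk$ka, lag = 0,
                                      formulation = "dissolved"),
                    processes = list(
                      adme_process("clearance_renal", site = "central",
                                   rate = pk$cl / pk$volume)))
  build_model(phys, drug)
}

#' Generate noisy oral-dose concentration observations
#'
#' Simulates the configured one-compartment oral model and perturbs the
#' sampled concentrations with proportional log-normal error:
#' `C_obs = C_true * exp(eps)`, `eps ~ N(0, cv)`.
#'
#' @param cfg a [synth_config()].
#' @return data.frame with `time` (min), `conc_true` and `conc_obs`
#'   (umol/L); attributes carry the true parameters.
#' @export
gen_pk_observations <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  pk <- cfg$pk
  model <- toy_pk_model(pk)
  span <- max(pk$times)
  prof <- simulate_pbpk(model, dose_event("oral", pk$dose_mg), span = span,
                        dt = min(1, min(diff(c(0, sort(pk$times))))))
  cc <- get_conc(prof, "toy", "central")
  truth <- stats::approx(cc$time, cc$conc, xout = pk$times)$y
  set.seed(cfg$seed)
  eps <- stats::rnorm(length(pk$times), 0, pk$cv)
  out <- data.frame(time = pk$times, conc_true = truth,
                    conc_obs = truth * exp(eps))
  attr(out, "true_cl") <- pk$cl
  attr(out, "true_ka") <- pk$ka
  attr(out, "pk") <- pk
  out
}

#' Calibrate the toy one-compartment model to observations
#'
#' Least-squares on the log scale (matching the log-normal error model)
#' over clearance and absorption rate with the volume fixed at its known
#' value; used to demonstrate parameter recovery from noisy synthetic
#' profiles.
#'
#' @param obs output of [gen_pk_observations()].
#' @param pk the generating PK config (defaults to the one attached to
#'   `obs`); `cl` and `ka` entries are used as starting values.
#' @return list with `cl`, `ka`, and the `optim` convergence code.
#' @export
calibrate_toy_pk <- function(obs, pk = attr(obs, "pk")) {
  stopifnot(!is.null(pk))
  objective <- function(par) {
    pk2 <- pk
    pk2$cl <- exp(par[1]); pk2$ka <- exp(par[2])
    model <- toy_pk_model(pk2)
    prof <- simulate_pbpk(model, dose_event("oral", pk2$dose_mg),
                          span = max(obs$time), dt = 1,
                          rtol = 1e-6, atol = 1e-8)
    cc <- get_conc(prof, "toy", "central")
    pred <- stats::approx(cc$time, cc$conc, xout = obs$time)$y
    if (any(pred <= 0)) return(1e6)
    sum((log(pred) - log(obs$conc_obs))^2)
  }
  st <- log(c(pk$cl * 1.5, pk$ka * 0.7))
  opt <- stats::optim(st, objective, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-8))
  list(cl = exp(opt$par[1]), ka = exp(opt$par[2]),
       convergence = opt$convergence)
}

#' Generate synthetic pain-relief pairs from a Hill curve
#'
#' @param cfg a [synth_config()].
#' @return data.frame with columns `x` (PGE2 decrease) and `y` (pain
#'   relief minus placebo); attribute `truth` holds the generating
#'   parameters.
#' @export
gen_pain_relief <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  pn <- cfg$pain
  set.seed(cfg$seed + 1L)
  x <- stats::runif(pn$n, 0, pn$x_max)
  y <- evaluate_hill(pn, x) + stats::rnorm(pn$n, 0, pn$sigma)
  out <- data.frame(x = x, y = y)
  attr(out, "truth") <- c(a = pn$a, b = pn$b, c = pn$c)
  out
}

#' Toy inhibition network with an algebraic steady state
#'
#' A source pool feeds an arachidonic-acid node that drains through a
#' COX-2 branch (to PGE2) and a 5-LOX branch (to wLTB4), each mediator
#' being degraded enzymatically; both branch reactions share one Km so the
#' uninhibited steady state has a closed form, and under a constant
#' competitive COX-2 inhibitor the branch-node balance reduces to a
#' quadratic (see [toy_steady_state()]).  No feedback edges.
#'
#' @param cfg a [synth_config()].
#' @return list with `network` (a [network_model()]) and `steady_state`
#'   (named vector, the uninhibited steady state from the algebraic
#'   oracle).
#' @export
gen_toy_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!identical(cfg$network$id, "linear_chain"))
    stop("gen_toy_network: unknown toy network id '", cfg$network$id, "'",
         call. = FALSE)
  species <- data.frame(
    name = c("SRC", "AA", "PGE2", "wLTB4"),
    initial = c(100, 1, 1, 1),
    boundary = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  reactions <- list(
    mm_reaction("input", "SRC", "AA", "PLA2", vmax = 0.5, km = 150),
    mm_reaction("cox2", "AA", "PGE2", "COX-2", vmax = 2.0, km = 40),
    mm_reaction("lox5", "AA", "wLTB4", "5-LOX", vmax = 1.5, km = 40),
    mm_reaction("pge2_deg", "PGE2", NULL, "15-PGDH", vmax = 0.8, km = 60),
    mm_reaction("wltb4_deg", "wLTB4", NULL, "wLTB4-deg", vmax = 0.6,
                km = 50))
  net <- network_model(species, reactions, feedback = list(),
                       provenance = "packaged_surrogate")
  ss <- toy_steady_state(net)
  net$species$initial <- unname(ss[net$species$name])
  list(network = net, steady_state = ss)
}

#' Algebraic steady state of the toy network
#'
#' Flux balance: the constant input flux v_in splits over the two branch
#' reactions; with a common branch Km the AA balance
#' `v_in = (V_cox + V_lox') * AA / (Km + AA)` inverts in closed form, and
#' with a COX-2 inhibition factor (Km scaled by `1 + I/Ki`) it becomes a
#' quadratic whose positive root is taken.  Mediator levels follow by
#' inverting their degradation kinetics.  Independent of the ODE solver.
#'
#' @param net the toy network from [gen_toy_network()].
#' @param inhibition_factor competitive factor `1 + I/Ki` applied to the
#'   COX-2 branch Km (1 = no inhibition).
#' @return named vector of steady-state concentrations.
#' @export
toy_steady_state <- function(net, inhibition_factor = 1) {
  r <- stats::setNames(net$reactions,
                       vapply(net$reactions, `[[`, "", "name"))
  src <- net$species$initial[net$species$name == "SRC"]
  v_in <- r$input$vmax * src / (r$input$km + src)
  k_cox <- r$cox2$km * inhibition_factor
  k_lox <- r$lox5$km
  V1 <- r$cox2$vmax; V2 <- r$lox5$vmax
  # (V1 + V2 - v_in) AA^2 + (V1 k_lox + V2 k_cox - v_in (k_cox + k_lox)) AA
  #   - v_in k_cox k_lox = 0
  A2 <- V1 + V2 - v_in
  A1 <- V1 * k_lox + V2 * k_cox - v_in * (k_cox + k_lox)
  A0 <- -v_in * k_cox * k_lox
  if (A2 <= 0)
    stop("toy_steady_state: input flux exceeds branch capacity",
         call. = FALSE)
  aa <- (-A1 + sqrt(A1^2 - 4 * A2 * A0)) / (2 * A2)
  f_cox <- V1 * aa / (k_cox + aa)
  f_lox <- V2 * aa / (k_lox + aa)
  invert_mm <- function(reac, flux) {
    if (flux >= reac$vmax)
      stop("toy_steady_state: degradation capacity exceeded", call. = FALSE)
    reac$km * flux / (reac$vmax - flux)
  }
  c(SRC = src, AA = aa,
    PGE2 = invert_mm(r$pge2_deg, f_cox),
    wLTB4 = invert_mm(r$wltb4_deg, f_lox))
}
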