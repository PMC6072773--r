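#' Cellular network models of arachidonic-acid metabolism
#'
#' A `network_model` is an ODE system of Michaelis-Menten reactions over a
#' set of species, optionally modulated by feedback edges and inhibited
#' competitively by time-varying drug signals.  Two sources are supported:
#' import from SBML (see [read_sbml_network()]) and the packaged surrogate
#' network [surrogate_network()], a reduced COX-2/5-LOX branch model whose
#' parameters are defined in this repository.
#'
#' @param species data.frame with columns `name`, `initial` (umol/L) and
#'   `boundary` (logical; boundary species are held constant).
#' @param reactions list of [mm_reaction()] objects.
#' @param feedback list of feedback edges, each a list with `regulator`
#'   (species), `target` (reaction name), `sign` (+1 activating, -1
#'   inhibiting), `strength` (>= 0) and `k_half` (umol/L): the target
#'   reaction rate is multiplied by `1 + sign * strength * R/(k_half + R)`
#'   (floored at zero).
#' @param provenance `"packaged_surrogate"` or `"sbml_import"`.
#' @return an object of class `network_model`.
#' @export
network_model <- function(species, reactions, feedback = list(),
                          provenance = "packaged_surrogate") {
  obj <- structure(list(species = species, reactions = reactions,
                        feedback = feedback, provenance = provenance),
                   class = "network_model")
  validate_network(obj)
  obj
}

#' Michaelis-Menten reaction
#'
#' @param name reaction identifier (unique).
#' @param substrate,product species names; `product = NULL` marks efflux to
#'   a sink outside the modelled species set.
#' @param enzyme enzyme label (e.g. `"COX-2"`, `"5-LOX"`); inhibitor
#'   signals attach by this label.
#' @param vmax maximal rate (umol/L/min, >= 0).
#' @param km Michaelis constant (umol/L, > 0).
#' @return an object of class `mm_reaction`.
#' @export
mm_reaction <- function(name, substrate, product, enzyme, vmax, km) {
  if (vmax < 0) stop("mm_reaction '", name, "': vmax must be >= 0",
                     call. = FALSE)
  if (km <= 0) stop("mm_reaction '", name, "': km must be > 0",
                    call. = FALSE)
  structure(list(name = name, substrate = substrate, product = product,
                 enzyme = enzyme, vmax = vmax, km = km),
            class = "mm_reaction")
}

#' Validate a network model
#' @param net a `network_model`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  sp <- net$species
  stopifnot(is.data.frame(sp),
            all(c("name", "initial", "boundary") %in% names(sp)))
  if (any(sp$initial < 0))
    stop("network: negative initial concentration for ",
         paste(sp$name[sp$initial < 0], collapse = ", "), call. = FALSE)
  rn <- vapply(net$reactions, function(r) r$name, character(1))
  if (anyDuplicated(rn))
    stop("network: duplicate reaction names", call. = FALSE)
  for (r in net$reactions) {
    for (s in c(r$substrate, r$product)) {
      if (!is.null(s) && !s %in% sp$name)
        stop("network: reaction '", r$name, "' references unknown species '",
             s, "'", call. = FALSE)
    }
  }
  for (fb in net$feedback) {
    if (!fb$regulator %in% sp$name)
      stop("network: feedback regulator '", fb$regulator,
           "' is not a species", call. = FALSE)
    if (!fb$target %in% rn)
      stop("network: feedback target '", fb$target,
           "' is not a reaction", call. = FALSE)
    if (!fb$sign %in% c(-1, 1))
      stop("network: feedback sign must be +1 or -1", call. = FALSE)
    if (fb$strength < 0 || fb$k_half <= 0)
      stop("network: feedback strength must be >= 0 and k_half > 0",
           call. = FALSE)
  }
  for (needed in c("PGE2", "wLTB4")) {
    if (!needed %in% sp$name)
      stop("network: species set must include ", needed, call. = FALSE)
  }
  invisible(net)
}

#' Packaged surrogate network of arachidonic-acid metabolism
#'
#' A reduced, self-contained stand-in for literature leukocyte models: a
#' phospholipid pool feeds a shared arachidonic-acid (AA) pool; the COX-2
#' branch converts AA to PGE2 and the 5-LOX branch converts AA via LTB4 to
#' omega-oxidised LTB4 (`wLTB4`); both mediators are degraded
#' enzymatically.  Most liberated AA is re-esterified back into the
#' phospholipid pool (the Lands cycle), so the free AA pool is buffered
#' and the branch fluxes respond near-proportionally to COX-2/5-LOX
#' inhibition instead of being pinned by the release flux.  Substrate
#' levels sit far below every Km, so inhibition of COX-2 and 5-LOX
#' operates in the unsaturated regime where the competitive Km scaling
#' dominates.  Two feedback edges close the loop: PGE2 dampens the 5-LOX
#' branch and LTB4 stimulates AA release.  All parameter values are
#' repository-defined, not literature values.
#'
#' @return a `network_model` at its (approximate) steady state.
#' @export
surrogate_network <- function() {
  species <- data.frame(
    name = c("PL", "AA", "PGE2", "LTB4", "wLTB4"),
    initial = c(100, 0.97144155, 1.66764268, 1.40002345, 1.87294117),
    boundary = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  reactions <- list(
    mm_reaction("aa_release", "PL", "AA", "PLA2", vmax = 10.0, km = 400),
    mm_reaction("aa_reacylation", "AA", "PL", "LPCAT", vmax = 60.0,
                km = 30),
    mm_reaction("cox2_pge2", "AA", "PGE2", "COX-2", vmax = 6.0, km = 50),
    mm_reaction("lox5_ltb4", "AA", "LTB4", "5-LOX", vmax = 5.0, km = 50),
    mm_reaction("ltb4_omega", "LTB4", "wLTB4", "CYP4F3", vmax = 4.0,
                km = 60),
    mm_reaction("pge2_deg", "PGE2", NULL, "15-PGDH", vmax = 5.6, km = 80),
    mm_reaction("wltb4_deg", "wLTB4", NULL, "wLTB4-deg", vmax = 3.5,
                km = 70))
  feedback <- list(
    list(regulator = "PGE2", target = "lox5_ltb4", sign = -1,
         strength = 0.30, k_half = 10),
    list(regulator = "LTB4", target = "aa_release", sign = +1,
         strength = 0.20, k_half = 5))
  network_model(species, reactions, feedback,
                provenance = "packaged_surrogate")
}

#' Time-varying inhibitor signal for competitive inhibition
#'
#' Couples an unbound drug concentration-time course to a target enzyme
#' with a binding affinity Ki.  The contribution is exactly zero before the
#' oral-cavity residence delay (default 5 min) has elapsed after dosing.
#'
#' @param drug drug name.
#' @param enzyme target enzyme label (`"COX-2"`, `"5-LOX"`).
#' @param ki binding affinity (umol/L, > 0).
#' @param conc either a function of time (min) returning unbound
#'   concentration (umol/L) or a data.frame with `time`/`conc` columns.
#' @param t_dose time of (first) dosing on the signal's clock (min).
#' @param onset_delay inhibition onset delay after dosing (min).
#' @return an object of class `inhibitor_signal`; calling
#'   `signal_conc(sig, t)` evaluates the effective inhibitor concentration.
#' @export
inhibitor_signal <- function(drug, enzyme, ki, conc, t_dose = 0,
                             onset_delay = 5) {
  if (ki <= 0) stop("inhibitor_signal: ki must be > 0", call. = FALSE)
  if (is.data.frame(conc)) {
    stopifnot(all(c("time", "conc") %in% names(conc)))
    if (any(conc$conc < -1e-12))
      stop("inhibitor_signal: negative concentrations", call. = FALSE)
    conc_fun <- stats::approxfun(conc$time, pmax(conc$conc, 0), rule = 2)
  } else if (is.function(conc)) {
    conc_fun <- conc
  } else stop("inhibitor_signal: conc must be a function or a data.frame",
              call. = FALSE)
  structure(list(drug = drug, enzyme = enzyme, ki = ki,
                 conc_fun = conc_fun, t_dose = t_dose,
                 onset_delay = onset_delay),
            class = "inhibitor_signal")
}

#' Effective inhibitor concentration of a signal at time t
#' @param sig an `inhibitor_signal`.
#' @param t time (min), scalar or vector.
#' @return concentration (umol/L); zero before `t_dose + onset_delay`.
#' @export
signal_conc <- function(sig, t) {
  out <- pmax(sig$conc_fun(t), 0)
  out[t < sig$t_dose + sig$onset_delay] <- 0
  out
}

#' Effective Michaelis constant under competitive inhibition
#'
#' Multiple inhibitors of the same enzyme combine additively in the
#' inhibition term: `Km_eff(t) = Km * (1 + sum_i I_i(t) / Ki_i)`.
#'
#' @param reaction an [mm_reaction()].
#' @param signals list of [inhibitor_signal()]s (any enzymes; signals not
#'   matching the reaction's enzyme are ignored).
#' @param t time (min), scalar or vector.
#' @return Km_eff at `t` (umol/L).
#' @export
effective_km <- function(reaction, signals, t) {
  rel <- Filter(function(s) identical(s$enzyme, reaction$enzyme), signals)
  term <- 0
  for (s in rel) term <- term + signal_conc(s, t) / s$ki
  reaction$km * (1 + term)
}

# reaction-rate vector at time t given state S (named), internal
network_rates <- function(net, S, t, signals) {
  vapply(net$reactions, function(r) {
    sub <- S[[r$substrate]]
    if (sub <= 0) return(0)
    mod <- 1
    for (fb in net$feedback) {
      if (fb$target == r$name) {
        R <- max(S[[fb$regulator]], 0)
        mod <- mod * (1 + fb$sign * fb$strength * R / (fb$k_half + R))
      }
    }
    mod <- max(mod, 0)
    km_eff <- effective_km(r, signals, t)
    r$vmax * mod * sub / (km_eff + sub)
  }, numeric(1))
}

#' Simulate the network under time-varying competitive inhibition
#'
#' The network is first pre-equilibrated (burn-in without any inhibitor),
#' then integrated over `[0, span]` with the given signals; the paired
#' control run is the identical call with `signals = list()`, so control
#' and treated trajectories differ only through the inhibition term.
#'
#' @param net a `network_model`.
#' @param signals list of [inhibitor_signal()]s (empty = control run).
#' @param span simulated duration (min).
#' @param dt output resolution (min).
#' @param burn_in pre-equilibration time before t = 0 (min).
#' @param label run label stored on the result.
#' @param rtol,atol solver tolerances.
#' @return a `mediator_profile`: data.frame of all species over time with
#'   attributes `label` and `network`.
#' @export
simulate_network <- function(net, signals = list(), span = 360, dt = 1,
                             burn_in = 1440, label = if (length(signals))
                               "drug-treated" else "control",
                             rtol = 1e-8, atol = 1e-10) {
  validate_network(net)
  sp <- net$species
  free <- !sp$boundary
  y0 <- stats::setNames(sp$initial, sp$name)

  rhs <- function(t, y, parms, sigs) {
    S <- as.list(y)
    v <- network_rates(net, S, t, sigs)
    dy <- stats::setNames(numeric(length(y)), names(y))
    for (j in seq_along(net$reactions)) {
      r <- net$reactions[[j]]
      dy[r$substrate] <- dy[r$substrate] - v[j]
      if (!is.null(r$product)) dy[r$product] <- dy[r$product] + v[j]
    }
    dy[sp$name[sp$boundary]] <- 0
    list(dy)
  }

  if (burn_in > 0) {
    eq <- deSolve::lsoda(y0, times = c(0, burn_in), func = rhs,
                         parms = NULL, sigs = list(),
                         rtol = rtol, atol = atol, maxsteps = 50000)
    y0 <- eq[nrow(eq), -1]
    names(y0) <- sp$name
  }
  times <- seq(0, span, by = dt)
  if (times[length(times)] < span) times <- c(times, span)
  sol <- deSolve::lsoda(y0, times = times, func = rhs, parms = NULL,
                        sigs = signals, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  neg <- vapply(sp$name, function(nm) min(out[[nm]]), numeric(1))
  if (any(neg < -1e-6))
    stop("simulate_network: negative excursion for species ",
         names(neg)[which.min(neg)], " (", signif(min(neg), 3), ")",
         call. = FALSE)
  for (nm in sp$name) out[[nm]] <- pmax(out[[nm]], 0)
  structure(out, label = label, network = net$provenance,
            class = c("mediator_profile", "data.frame"))
}
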