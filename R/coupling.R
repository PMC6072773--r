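#' Drug efficacy score (DES)
#'
#' The efficacy of a treatment at time t is the mean of the fractional
#' reductions of the two inflammatory mediators relative to the paired
#' drug-free control:
#'
#' \deqn{DES(t) = \frac{1}{2}\left(\frac{PGE2_c - PGE2_d}{PGE2_c} +
#'   \frac{\omega LTB4_c - \omega LTB4_d}{\omega LTB4_c}\right)}
#'
#' @param control,treated `mediator_profile` objects on the same grid.
#' @param t evaluation time(s) in minutes; `NULL` evaluates the whole grid.
#' @param mediators the two mediator species names.
#' @return numeric DES value(s).
#' @export
compute_des <- function(control, treated, t = NULL,
                        mediators = c("PGE2", "wLTB4")) {
  if (!isTRUE(all.equal(control$time, treated$time)))
    stop("compute_des: control and treated profiles must share the grid",
         call. = FALSE)
  idx <- if (is.null(t)) seq_along(control$time) else {
    i <- match(TRUE, abs(control$time - t[1]) < 1e-9)
    if (length(t) > 1 || is.na(i))
      idx <- vapply(t, function(tt) {
        j <- which.min(abs(control$time - tt))
        if (abs(control$time[j] - tt) > 1e-6)
          stop("compute_des: time ", tt, " not on the profile grid",
               call. = FALSE)
        j
      }, integer(1))
    else i
  }
  terms <- vapply(mediators, function(md) {
    cc <- control[[md]][idx]
    dd <- treated[[md]][idx]
    if (any(cc <= 0))
      stop("compute_des: control ", md, " is zero; DES undefined",
           call. = FALSE)
    (cc - dd) / cc
  }, numeric(length(idx)))
  if (is.null(dim(terms))) sum(terms) / 2 else rowSums(terms) / 2
}

parse_scenario_config <- function(cfg, path = "<config>") {
  req <- c("id", "label", "drugs")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("scenario config ", path, ": missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  drugs <- lapply(cfg$drugs, function(d) {
    if (is.null(d$drug) || is.null(d$dose_mg))
      stop("scenario config ", path, ": each drugs entry needs drug/dose_mg",
           call. = FALSE)
    if (d$dose_mg <= 0)
      stop("scenario config ", path, ": drugs.dose_mg must be > 0",
           call. = FALSE)
    list(drug = d$drug, dose_mg = d$dose_mg, route = d$route %||% "oral",
         repeat_interval = d$repeat_interval, repeat_count =
           d$repeat_count %||% 1,
         coupling_compartment = d$coupling_compartment %||% "venous_cells")
  })
  pre <- cfg$pretreatment
  if (!is.null(pre)) {
    if (is.null(pre$dose_mg) || is.null(pre$days))
      stop("scenario config ", path,
           ": pretreatment needs dose_mg and days", call. = FALSE)
    pre <- list(drug = pre$drug %||% "rifampicin", dose_mg = pre$dose_mg,
                days = pre$days, interval_min = pre$interval_min %||% 1440)
  }
  structure(list(id = cfg$id, label = cfg$label, drugs = drugs,
                 pretreatment = pre,
                 horizon_h = cfg$horizon_h %||% 6,
                 result = cfg$result %||% "drug_efficacy"),
            class = "scenario")
}

#' Load a packaged therapeutic scenario
#'
#' The packaged registry holds the eleven therapeutic situations studied
#' by the pipeline (single and co-treatment of COX-2/5-LOX inhibitors,
#' rifampicin drug-interaction arms, and the correlation-study arms).
#'
#' @param id scenario id (1-11) or a path to a scenario YAML.
#' @return an object of class `scenario`.
#' @export
load_scenario <- function(id) {
  path <- if (is.character(id) && file.exists(id)) id else
    extdata_path("scenarios", sprintf("scenario_%02d.yaml", as.integer(id)))
  if (!file.exists(path))
    stop("load_scenario: no packaged scenario '", id, "'", call. = FALSE)
  parse_scenario_config(yaml::read_yaml(path), path)
}

#' The full packaged scenario registry
#' @return named list of the eleven packaged `scenario` objects.
#' @export
scenario_registry <- function() {
  files <- sort(list.files(extdata_path("scenarios"),
                           pattern = "^scenario_\\d+\\.yaml$",
                           full.names = TRUE))
  sc <- lapply(files, load_scenario)
  names(sc) <- vapply(sc, function(s) as.character(s$id), character(1))
  sc
}

#' Compute perpetrator-driven CYP activity folds for a scenario
#'
#' Simulates the rifampicin pre-treatment PBPK (oral q.d. dosing over the
#' configured number of days), feeds the unbound intracellular liver
#' concentration into the PXR cascade, and extends the CYP3A4 fold to the
#' other CYPs by increment scaling.  The returned folds run on the
#' pre-treatment clock; the victim dose time is attached as attribute
#' `t_victim` (24 h after the last perpetrator dose).
#'
#' @param sc a `scenario` with a pre-treatment block.
#' @param phys physiology used for the perpetrator simulation.
#' @param params PXR cascade parameters.
#' @param ratios induction ratios for the non-CYP3A4 enzymes.
#' @param dt output resolution (min).
#' @return an [activity_fold()] with attribute `t_victim`, or `NULL` when
#'   the scenario has no pre-treatment.
#' @export
induction_folds <- function(sc, phys = default_physiology(),
                            params = pxr_params(),
                            ratios = default_induction_ratios(), dt = 5) {
  if (is.null(sc$pretreatment)) return(NULL)
  pre <- sc$pretreatment
  perp <- load_drug(pre$drug)
  t_victim <- pre$days * pre$interval_min
  span <- t_victim + sc$horizon_h * 60 + 60
  model <- build_model(phys, perp$spec)
  prof <- simulate_pbpk(model,
                        dose_event("oral", pre$dose_mg, time = 0,
                                   repeat_interval = pre$interval_min,
                                   repeat_count = pre$days),
                        span = span, dt = dt)
  liver <- get_conc(prof, perp$spec$name, "liver_intracellular", "unbound")
  f3 <- simulate_induction(data.frame(time = liver$time, conc = liver$conc),
                           params = params)
  folds <- extend_to_other_cyps(f3, ratios)
  attr(folds, "t_victim") <- t_victim
  folds
}

#' Run one therapeutic scenario end-to-end
#'
#' Pipeline per scenario: perpetrator pre-treatment (if any) -> CYP
#' activity folds -> induced victim PBPK runs -> unbound venous blood-cell
#' inhibitor signals with the 5-min oral-cavity onset delay -> paired
#' control/treated network simulations -> DES(t).
#'
#' @param sc a `scenario` (see [load_scenario()]).
#' @param network a [network_model()]; defaults to the packaged surrogate.
#' @param phys a [physiology()].
#' @param folds pre-computed [induction_folds()] result (recomputed when
#'   `NULL` and the scenario has a pre-treatment).
#' @param dose_multiplier scalar multiplying every victim dose (used by
#'   dose escalation and dose-adjustment searches).
#' @param dt output grid resolution (min).
#' @return an object of class `efficacy_result`: mediator profiles
#'   (control and treated), `des` data.frame over the grid, DES at 0.5 h
#'   and at the horizon, and the per-drug PK profiles.
#' @export
run_scenario <- function(sc, network = surrogate_network(),
                         phys = default_physiology(), folds = NULL,
                         dose_multiplier = 1, dt = 1) {
  stopifnot(inherits(sc, "scenario"), dose_multiplier > 0)
  horizon <- sc$horizon_h * 60
  if (is.null(folds) && !is.null(sc$pretreatment))
    folds <- induction_folds(sc, phys = phys)
  t_victim <- attr(folds, "t_victim") %||% 0

  signals <- list()
  pk <- list()
  for (dr in sc$drugs) {
    cfgd <- load_drug(dr$drug)
    model <- build_model(phys, cfgd$spec)
    if (!is.null(folds))
      model <- apply_cyp_induction(model, folds, t_offset = t_victim)
    prof <- simulate_pbpk(model,
                          dose_event(dr$route, dr$dose_mg * dose_multiplier,
                                     repeat_interval = dr$repeat_interval,
                                     repeat_count = dr$repeat_count %||% 1),
                          span = horizon, dt = dt)
    pk[[dr$drug]] <- prof
    cells <- get_conc(prof, cfgd$spec$name,
                      dr$coupling_compartment %||% "venous_cells",
                      "unbound")
    if (is.null(cfgd$targets))
      stop("run_scenario: drug '", dr$drug, "' declares no inhibition ",
           "targets", call. = FALSE)
    for (k in seq_len(nrow(cfgd$targets))) {
      signals[[length(signals) + 1]] <- inhibitor_signal(
        drug = cfgd$spec$name, enzyme = cfgd$targets$enzyme[k],
        ki = cfgd$targets$ki[k],
        conc = cells, t_dose = 0, onset_delay = 5)
    }
  }

  control <- simulate_network(network, list(), span = horizon, dt = dt)
  treated <- simulate_network(network, signals, span = horizon, dt = dt)
  des <- data.frame(time = control$time,
                    des = compute_des(control, treated))
  at <- function(t_h) {
    tt <- t_h * 60
    if (tt > horizon) return(NA_real_)
    des$des[which.min(abs(des$time - tt))]
  }
  structure(list(id = sc$id, label = sc$label, scenario = sc,
                 control = control, treated = treated, des = des,
                 des_at = c(`0.5h` = at(0.5),
                            horizon = at(sc$horizon_h)),
                 dose_multiplier = dose_multiplier,
                 signals = signals, pk = pk, folds = folds),
            class = "efficacy_result")
}

#' @export
print.efficacy_result <- function(x, ...) {
  cat(sprintf("<efficacy_result> scenario %s (%s): DES(0.5 h) = %.3f, DES(%g h) = %.3f\n",
              x$id, x$label, x$des_at[["0.5h"]], x$scenario$horizon_h,
              x$des_at[["horizon"]]))
  invisible(x)
}

#' Dose-escalation study for a scenario
#'
#' Runs the scenario at a grid of dose fractions of the therapeutic dose
#' and reports the DES at the evaluation horizon; the final grid point 1.0
#' reproduces the plain scenario result.
#'
#' @param sc a `scenario`.
#' @param fractions sorted dose fractions in (0, 1].
#' @param ... passed to [run_scenario()].
#' @return data.frame with columns `fraction`, `des_horizon`, `des_05h`.
#' @export
dose_escalation <- function(sc, fractions = c(0.05, 0.1, 0.25, 0.5,
                                              0.75, 1.0), ...) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions))
  args <- list(...)
  if (is.null(args$folds) && !is.null(sc$pretreatment))
    args$folds <- induction_folds(sc)
  rows <- lapply(fractions, function(f) {
    r <- do.call(run_scenario,
                 c(list(sc = sc, dose_multiplier = f), args))
    data.frame(fraction = f, des_horizon = r$des_at[["horizon"]],
               des_05h = r$des_at[["0.5h"]])
  })
  do.call(rbind, rows)
}

#' Dose-adjustment search for a drug-interaction scenario
#'
#' Finds the smallest dose multiplier m such that the DDI scenario dosed
#' at m times the label dose reaches the reference scenario's DES at the
#' evaluation time, by bisection on the (numerically verified) monotone
#' DES-vs-dose relationship.
#'
#' @param sc_ddi scenario with the interaction (e.g. rifampicin arm).
#' @param sc_ref reference scenario without the interaction.
#' @param t_h evaluation time (h).
#' @param bracket multiplier search bracket.
#' @param tol_des bisection stops when |DES - target| < `tol_des`.
#' @param max_iter maximum bisection iterations.
#' @param ... passed to [run_scenario()] (network, physiology, dt).
#' @return list with `multiplier`, `multiplier_rounded` (0.5 steps),
#'   `des_target`, `des_achieved`, `iterations`.
#' @export
dose_adjustment_search <- function(sc_ddi, sc_ref, t_h = 6,
                                   bracket = c(1, 8), tol_des = 1e-3,
                                   max_iter = 40, ...) {
  args <- list(...)
  if (is.null(args$folds) && !is.null(sc_ddi$pretreatment))
    args$folds <- induction_folds(sc_ddi)
  folds_ddi <- args$folds
  ref <- do.call(run_scenario, c(list(sc = sc_ref), args[names(args) !=
                                                           "folds"]))
  target <- des_at_time(ref, t_h)
  f <- function(m) {
    r <- do.call(run_scenario,
                 c(list(sc = sc_ddi, dose_multiplier = m,
                        folds = folds_ddi),
                   args[names(args) != "folds"]))
    des_at_time(r, t_h)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f(lo)
  if (abs(f_lo - target) < tol_des)
    return(list(multiplier = lo, multiplier_rounded = round(lo * 2) / 2,
                des_target = target, des_achieved = f_lo, iterations = 0))
  f_hi <- f(hi)
  # numerical monotonicity check across the bracket
  f_mid0 <- f((lo + hi) / 2)
  if (!(f_lo <= f_mid0 + tol_des && f_mid0 <= f_hi + tol_des))
    stop("dose_adjustment_search: DES is not monotone in dose over the ",
         "bracket", call. = FALSE)
  if (target < f_lo - tol_des || target > f_hi + tol_des)
    stop("dose_adjustment_search: no solution in bracket [", lo, ", ", hi,
         "]; achieved DES range [", signif(f_lo, 4), ", ",
         signif(f_hi, 4), "], target ", signif(target, 4), call. = FALSE)
  it <- 0
  m <- (lo + hi) / 2
  repeat {
    it <- it + 1
    fm <- f(m)
    if (abs(fm - target) < tol_des || it >= max_iter) break
    if (fm < target) lo <- m else hi <- m
    m <- (lo + hi) / 2
  }
  list(multiplier = m, multiplier_rounded = round(m * 2) / 2,
       des_target = target, des_achieved = fm, iterations = it)
}

des_at_time <- function(res, t_h) {
  res$des$des[which.min(abs(res$des$time - t_h * 60))]
}

#' JSON summary of one or more efficacy results
#' @param results list of `efficacy_result` objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_efficacy_json <- function(results, path) {
  if (inherits(results, "efficacy_result")) results <- list(results)
  out <- lapply(results, function(r)
    list(scenario = r$id, label = r$label,
         des_05h = r$des_at[["0.5h"]],
         des_horizon = r$des_at[["horizon"]],
         horizon_h = r$scenario$horizon_h,
         dose_multiplier = r$dose_multiplier))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
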