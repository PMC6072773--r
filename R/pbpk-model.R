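#' Build a whole-body PBPK model for a drug and its metabolites
#'
#' Assembles the ODE right-hand side for the parent compound and every
#' metabolite in its (acyclic) metabolite tree over the compartment graph of
#' `phys`.  Distribution is perfusion-limited with plasma-referenced
#' partition coefficients; the liver is split into vascular, interstitial
#' and intracellular sub-compartments exchanging by permeability-surface
#' products, and venous blood cells exchange with venous plasma the same
#' way.  Enzyme-mediated rates are scaled by the physiology's
#' per-compartment enzyme expression, so a kcat adjustment (e.g. CYP
#' induction) propagates to every compartment expressing that enzyme.
#'
#' State variables are amounts (umol).  Besides one amount per compound and
#' compartment, the state carries cumulative eliminated amounts per route
#' and a formation accumulator per metabolism process; the latter make the
#' metabolite-bookkeeping and mass-balance invariants directly checkable.
#'
#' @param phys a [physiology()].
#' @param drug a [drug_spec()]; its process sites must exist in `phys`.
#' @param ps_liver,ps_cells permeability-surface products (L/min) for the
#'   liver sub-compartment chain and the venous plasma/blood-cell exchange.
#' @return an object of class `pbpk_model`.
#' @export
build_model <- function(phys, drug, ps_liver = 2, ps_cells = 1) {
  validate_physiology(phys)
  validate_drug_spec(drug)
  comps <- phys$compartments$name
  compounds <- flatten_compounds(drug)
  cn <- names(compounds)

  # check process sites / transport destinations / enzymes
  for (d in compounds) {
    for (p in d$processes) {
      if (!p$site %in% comps)
        stop("build_model: process site '", p$site, "' of compound '",
             d$name, "' is not a compartment of this physiology",
             call. = FALSE)
      if (!is.null(p$to) && !p$to %in% comps)
        stop("build_model: transport destination '", p$to,
             "' of compound '", d$name, "' is not a compartment",
             call. = FALSE)
      if (p$kind == "metabolism" &&
          !p$enzyme %in% names(phys$enzyme_expression))
        stop("build_model: enzyme '", p$enzyme, "' of compound '", d$name,
             "' has no expression entry in the physiology", call. = FALSE)
    }
  }

  n_comp <- length(comps)
  n_cpd <- length(cn)
  amount_names <- as.vector(outer(comps, cn, function(co, cp)
    paste0(cp, "|", co)))
  elim_routes <- c("renal", "hepatic", "biliary", "terminal")
  elim_names <- as.vector(outer(elim_routes, cn, function(r, cp)
    paste0("elim_", r, "|", cp)))

  # flat process table with pre-resolved indices
  proc <- list()
  k <- 0
  for (ci in seq_len(n_cpd)) {
    d <- compounds[[ci]]
    for (pi in seq_along(d$processes)) {
      p <- d$processes[[pi]]
      k <- k + 1
      site_i <- match(p$site, comps)
      row <- list(compound = ci, pid = paste0(d$name, ".", p$kind, ".", pi),
                  kind = p$kind, site = site_i, enzyme = p$enzyme,
                  km = p$km, rate = p$rate,
                  product = if (!is.null(p$product))
                    match(p$product, cn) else NA_integer_,
                  to = if (!is.null(p$to)) match(p$to, comps) else NA_integer_,
                  vmax_base = NA_real_)
      if (p$kind == "metabolism") {
        ex <- phys$enzyme_expression[[p$enzyme]]
        row$vmax_base <- p$kcat * p$enzyme_scale *
          (if (p$site %in% names(ex)) unname(ex[p$site]) else 0)
      }
      proc[[k]] <- row
    }
  }
  formed_names <- if (length(proc))
    paste0("formed|", vapply(proc, function(p) p$pid, character(1)))
  else character()
  formed_names <- formed_names[vapply(proc, function(p)
    p$kind == "metabolism", logical(1))]
  # map metabolism processes to their accumulator position
  met_ids <- which(vapply(proc, function(p) p$kind == "metabolism",
                          logical(1)))
  formed_index <- stats::setNames(seq_along(met_ids), met_ids)

  state_names <- c(amount_names, elim_names, formed_names)
  amt_idx <- matrix(seq_len(n_comp * n_cpd), nrow = n_comp, ncol = n_cpd,
                    dimnames = list(comps, cn))
  elim_idx <- matrix(n_comp * n_cpd + seq_len(4 * n_cpd), nrow = 4,
                     dimnames = list(elim_routes, cn))
  formed_off <- n_comp * n_cpd + 4 * n_cpd

  V <- phys$compartments$volume
  kp <- vapply(compounds, function(d) {
    out <- rep(1, n_comp)
    pc <- d$partition_coefficients
    hit <- match(names(pc), comps)
    if (anyNA(hit))
      stop("build_model: partition coefficient for unknown compartment '",
           names(pc)[is.na(hit)][1], "' (compound '", d$name, "')",
           call. = FALSE)
    out[hit] <- unname(pc)
    out
  }, numeric(n_comp))
  fu <- vapply(compounds, function(d) d$fraction_unbound, numeric(1))
  fu_cells <- vapply(compounds, function(d) d$fraction_unbound_cells,
                     numeric(1))
  ka <- vapply(compounds, function(d)
    if (is.null(d$absorption)) 0 else d$absorption$ka, numeric(1))

  structure(
    list(phys = phys, drug = drug, compounds = compounds,
         comps = comps, state_names = state_names,
         amt_idx = amt_idx, elim_idx = elim_idx, formed_off = formed_off,
         formed_index = formed_index, processes = proc,
         V = V, kp = kp, fu = fu, fu_cells = fu_cells, ka = ka,
         ps_liver = ps_liver, ps_cells = ps_cells,
         folds = list()),
    class = "pbpk_model")
}

#' Number of ADME processes in a model (or across several)
#' @param ... `pbpk_model` or `drug_spec` objects.
#' @return integer count of declared ADME processes.
#' @export
n_adme_processes <- function(...) {
  cnt1 <- function(x) {
    if (inherits(x, "pbpk_model")) return(length(x$processes))
    if (inherits(x, "drug_spec"))
      return(sum(vapply(flatten_compounds(x), function(d)
        length(d$processes), integer(1))))
    stop("n_adme_processes: unsupported object", call. = FALSE)
  }
  sum(vapply(list(...), cnt1, numeric(1)))
}

#' Scale CYP-mediated metabolism by induction folds
#'
#' Every metabolism process mediated by a listed enzyme has its kcat
#' multiplied by the enzyme's activity fold, time-varying or constant, in
#' every compartment expressing the enzyme (extrahepatic metabolism is
#' scaled along with hepatic).  Only induction (fold >= 1) is accepted.
#'
#' @param model a `pbpk_model`.
#' @param folds either a named numeric vector (constant fold per enzyme) or
#'   an [activity_fold()] object (time-resolved).
#' @param t_offset time shift (min) applied when evaluating a time-resolved
#'   fold: the PBPK simulation's `t` is looked up at `t + t_offset` on the
#'   fold's clock (used to align a victim-drug simulation with the end of a
#'   perpetrator pre-treatment).
#' @return the model with fold functions attached.
#' @export
apply_cyp_induction <- function(model, folds, t_offset = 0) {
  stopifnot(inherits(model, "pbpk_model"))
  fns <- list()
  if (inherits(folds, "activity_fold")) {
    for (enz in colnames(folds$fold)) {
      v <- folds$fold[, enz]
      if (any(v < 1 - 1e-9))
        stop("apply_cyp_induction: fold < 1 for ", enz,
             "; only induction is supported", call. = FALSE)
      f <- stats::approxfun(folds$time, v, rule = 2)
      fns[[enz]] <- local({
        f0 <- f; off <- t_offset
        function(t) f0(t + off)
      })
    }
  } else if (is.numeric(folds) && !is.null(names(folds))) {
    if (any(folds < 1 - 1e-9))
      stop("apply_cyp_induction: fold < 1; only induction is supported",
           call. = FALSE)
    for (enz in names(folds)) {
      fns[[enz]] <- local({ v <- unname(folds[[enz]]); function(t) v })
    }
  } else stop("apply_cyp_induction: folds must be a named numeric vector ",
              "or an activity_fold object", call. = FALSE)
  model$folds <- utils::modifyList(model$folds, fns)
  model
}

# right-hand side closure used by simulate(); internal
pbpk_rhs <- function(model) {
  comps <- model$comps
  n_comp <- length(comps)
  cn <- names(model$compounds)
  n_cpd <- length(cn)
  V <- model$V
  layout <- model$phys$layout
  amt_idx <- model$amt_idx
  elim_idx <- model$elim_idx
  formed_off <- model$formed_off
  formed_index <- model$formed_index
  proc <- model$processes

  i_of <- function(nm) match(nm, comps)
  if (layout == "whole_body") {
    i_art <- i_of("arterial_plasma"); i_ven <- i_of("venous_plasma")
    i_bc <- i_of("venous_cells"); i_lum <- i_of("gut_lumen")
    i_gw <- i_of("gut_wall"); i_lv <- i_of("liver_vascular")
    i_li <- i_of("liver_interstitial"); i_lc <- i_of("liver_intracellular")
    i_kid <- i_of("kidney"); i_per <- i_of("periphery")
    fl <- model$phys$compartments$flow
    Q_gut <- fl[i_gw]; Q_ha <- fl[i_lv]; Q_kid <- fl[i_kid]
    Q_per <- fl[i_per]
    Q_co <- Q_gut + Q_ha + Q_kid + Q_per
  } else {
    i_cen <- i_of("central"); i_lum <- i_of("gut_lumen")
  }
  ps_l <- model$ps_liver; ps_c <- model$ps_cells

  function(t, y, parms) {
    dy <- numeric(length(y))
    fold_cache <- list()
    fold_at <- function(enz) {
      f <- model$folds[[enz]]
      if (is.null(f)) return(1)
      if (is.null(fold_cache[[enz]])) fold_cache[[enz]] <<- f(t)
      fold_cache[[enz]]
    }
    for (ci in seq_len(n_cpd)) {
      ai <- amt_idx[, ci]
      A <- y[ai]
      C <- A / V
      kp <- model$kp[, ci]
      if (layout == "whole_body") {
        Cp <- C / kp           # plasma-equivalent outflow concentrations
        d <- numeric(n_comp)
        d[i_art] <- Q_co * (Cp[i_ven] - C[i_art])
        abs_flux <- model$ka[ci] * A[i_lum]
        d[i_lum] <- -abs_flux
        d[i_gw] <- abs_flux + Q_gut * (C[i_art] - Cp[i_gw])
        d[i_lv] <- Q_ha * C[i_art] + Q_gut * Cp[i_gw] -
          (Q_ha + Q_gut) * C[i_lv] + ps_l * (Cp[i_li] - C[i_lv])
        d[i_li] <- ps_l * (C[i_lv] - Cp[i_li]) +
          ps_l * (Cp[i_lc] - Cp[i_li])
        d[i_lc] <- ps_l * (Cp[i_li] - Cp[i_lc])
        d[i_kid] <- Q_kid * (C[i_art] - Cp[i_kid])
        d[i_per] <- Q_per * (C[i_art] - Cp[i_per])
        d[i_ven] <- (Q_ha + Q_gut) * C[i_lv] + Q_kid * Cp[i_kid] +
          Q_per * Cp[i_per] - Q_co * Cp[i_ven] +
          ps_c * (Cp[i_bc] - Cp[i_ven])
        d[i_bc] <- ps_c * (Cp[i_ven] - Cp[i_bc])
      } else {
        d <- numeric(n_comp)
        abs_flux <- model$ka[ci] * A[i_lum]
        d[i_lum] <- -abs_flux
        d[i_cen] <- abs_flux
      }
      dy[ai] <- dy[ai] + d
    }
    # ADME processes
    for (j in seq_along(proc)) {
      p <- proc[[j]]
      ai <- amt_idx[p$site, p$compound]
      A_site <- y[ai]
      if (p$kind == "metabolism") {
        if (p$vmax_base == 0) next
        fus <- if (comps[p$site] == "venous_cells")
          model$fu_cells[p$compound] else model$fu[p$compound]
        Cu <- fus * A_site / V[p$site]
        Cu <- max(Cu, 0)
        v <- p$vmax_base * fold_at(p$enzyme) * Cu / (p$km + Cu)
        dy[ai] <- dy[ai] - v
        if (!is.na(p$product)) {
          dy[amt_idx[p$site, p$product]] <-
            dy[amt_idx[p$site, p$product]] + v
        } else {
          dy[elim_idx["terminal", p$compound]] <-
            dy[elim_idx["terminal", p$compound]] + v
        }
        fi <- formed_off + formed_index[[as.character(j)]]
        dy[fi] <- dy[fi] + v
      } else if (p$kind %in% c("transport_influx", "transport_efflux")) {
        v <- p$rate * A_site
        dy[ai] <- dy[ai] - v
        ti <- amt_idx[p$to, p$compound]
        dy[ti] <- dy[ti] + v
      } else {
        route <- sub("clearance_", "", p$kind)
        v <- p$rate * A_site
        dy[ai] <- dy[ai] - v
        dy[elim_idx[route, p$compound]] <-
          dy[elim_idx[route, p$compound]] + v
      }
    }
    list(dy)
  }
}
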