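#' Non-compartmental PK metrics from a simulated profile
#'
#' Cmax and Tmax are read off the dense grid; AUC(0->inf) is the trapezoid
#' rule to the last grid point plus a terminal log-linear extrapolation
#' (C_last / lambda_z, with lambda_z fitted on the terminal decaying
#' stretch).  Concentrations are converted from umol/L to ng/ml through the
#' compound's molecular weight; times are reported in hours.
#'
#' If the terminal phase is not decaying, extrapolation is refused: the AUC
#' to the last time point is returned with `extrapolated = FALSE`.
#'
#' @param profile a `profile_set`.
#' @param compound compound name (default: the parent drug).
#' @param compartment compartment to evaluate (default venous plasma).
#' @param terminal_frac fraction of the post-Tmax tail used for the
#'   log-linear terminal fit.
#' @return an object of class `pk_metrics` with fields `cmax_ng_ml`,
#'   `tmax_h`, `auc_inf_ng_h_ml`, `extrapolated`, `auc_extra_frac`.
#' @export
pk_metrics <- function(profile, compound = NULL,
                       compartment = "venous_plasma",
                       terminal_frac = 0.25) {
  m <- profile$model
  compound <- compound %||% m$drug$name
  mw <- m$compounds[[compound]]$molecular_weight
  cc <- get_conc(profile, compound, compartment, "total")
  t_min <- cc$time
  conc <- umol_l_to_ng_ml(cc$conc, mw)
  if (length(t_min) < 3)
    stop("pk_metrics: profile must cover at least one dosing interval",
         call. = FALSE)

  i_max <- which.max(conc)
  cmax <- conc[i_max]
  tmax_h <- t_min[i_max] / 60
  t_h <- t_min / 60
  auc_last <- sum(diff(t_h) * (utils::head(conc, -1) + conc[-1]) / 2)

  # terminal log-linear fit on the tail after Tmax
  n <- length(conc)
  tail_start <- max(i_max + 1, floor(n * (1 - terminal_frac)))
  idx <- seq(tail_start, n)
  ok <- conc[idx] > 0
  extrapolated <- FALSE
  auc_extra <- 0
  if (sum(ok) >= 3 && conc[n] < 0.99 * cmax) {
    idx <- idx[ok]
    fit <- stats::lm.fit(cbind(1, t_h[idx]), log(conc[idx]))
    lambda_z <- -unname(fit$coefficients[2])
    if (is.finite(lambda_z) && lambda_z > 1e-8) {
      auc_extra <- conc[n] / lambda_z
      extrapolated <- TRUE
    }
  }
  if (!extrapolated)
    warning("pk_metrics: terminal phase not decaying; AUC reported to the ",
            "last time point only", call. = FALSE)
  auc_inf <- auc_last + auc_extra
  structure(list(cmax_ng_ml = cmax, tmax_h = tmax_h,
                 auc_inf_ng_h_ml = auc_inf,
                 extrapolated = extrapolated,
                 auc_extra_frac = auc_extra / auc_inf,
                 compound = compound, compartment = compartment),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf(
    "<pk_metrics> %s @ %s: Cmax = %.3g ng/ml, Tmax = %.3g h, AUCinf = %.3g ng*h/ml%s\n",
    x$compound, x$compartment, x$cmax_ng_ml, x$tmax_h, x$auc_inf_ng_h_ml,
    if (!x$extrapolated) " (no terminal extrapolation)" else ""))
  invisible(x)
}
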