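#' Rifampicin-PXR-CYP induction dynamics
#'
#' Rifampicin binding to the pregnane X receptor (PXR) in liver cells
#' up-regulates CYP transcription.  The module models this as a two-stage
#' turnover cascade driven by receptor occupancy of the intracellular
#' unbound rifampicin concentration C(t):
#'
#' \deqn{stim(C) = 1 + (Emax - 1) \cdot C / (EC50 + C)}
#' \deqn{dm/dt = k_{deg,m} (stim(C) - m), \quad de/dt = k_{deg,e} (m - e)}
#'
#' with mRNA (m) and enzyme (e) levels normalised to their baselines, so
#' the CYP3A4 activity fold is e(t) itself: fold = 1 without stimulus and
#' fold -> Emax under sustained saturating rifampicin.  Weaker induction of
#' other CYPs is obtained by scaling the CYP3A4 fold increment with
#' enzyme-specific induction ratios.
#'
#' @param ec50 PXR binding EC50 (umol/L); default 1.18.
#' @param emax maximal activity fold at saturation (>= 1).
#' @param mrna_halflife_h,enzyme_halflife_h turnover half-lives (h) of CYP
#'   mRNA and enzyme.
#' @return an object of class `pxr_params`.
#' @export
pxr_params <- function(ec50 = 1.18, emax = 8,
                       mrna_halflife_h = 6, enzyme_halflife_h = 36) {
  if (ec50 <= 0) stop("pxr_params: ec50 must be > 0", call. = FALSE)
  if (emax < 1) stop("pxr_params: emax must be >= 1", call. = FALSE)
  if (mrna_halflife_h <= 0 || enzyme_halflife_h <= 0)
    stop("pxr_params: turnover half-lives must be > 0", call. = FALSE)
  structure(list(ec50 = ec50, emax = emax,
                 kdeg_mrna = log(2) / (mrna_halflife_h * 60),
                 kdeg_enzyme = log(2) / (enzyme_halflife_h * 60)),
            class = "pxr_params")
}

#' Default induction ratios of other CYPs relative to CYP3A4
#'
#' @return named numeric vector of increment-scaling ratios in \[0, 1\].
#' @export
default_induction_ratios <- function() {
  c(CYP2C9 = 0.18, CYP2J2 = 0.03, CYP1A2 = 0.02)
}

#' Simulate CYP3A4 activity fold from an intracellular rifampicin profile
#'
#' @param rif_profile data.frame with `time` (min) and `conc` (umol/L,
#'   unbound intracellular liver rifampicin); must be non-negative.
#' @param params a [pxr_params()].
#' @param dt output resolution (min); defaults to the profile's grid.
#' @return an [activity_fold()] for enzyme `"CYP3A4"`.
#' @export
simulate_induction <- function(rif_profile, params = pxr_params(),
                               dt = NULL) {
  stopifnot(is.data.frame(rif_profile),
            all(c("time", "conc") %in% names(rif_profile)))
  if (any(rif_profile$conc < -1e-12))
    stop("simulate_induction: negative rifampicin concentrations",
         call. = FALSE)
  cfun <- stats::approxfun(rif_profile$time, pmax(rif_profile$conc, 0),
                           rule = 2)
  rhs <- function(t, y, p) {
    C <- cfun(t)
    stim <- 1 + (params$emax - 1) * C / (params$ec50 + C)
    list(c(m = params$kdeg_mrna * (stim - y[1]),
           e = params$kdeg_enzyme * (y[1] - y[2])))
  }
  t0 <- min(rif_profile$time); t1 <- max(rif_profile$time)
  times <- if (is.null(dt)) rif_profile$time else {
    tt <- seq(t0, t1, by = dt)
    if (tt[length(tt)] < t1) c(tt, t1) else tt
  }
  sol <- deSolve::lsoda(c(m = 1, e = 1), times = times, func = rhs,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  activity_fold(time = sol[, "time"],
                fold = matrix(pmax(sol[, "e"], 1),
                              dimnames = list(NULL, "CYP3A4")))
}

#' Time-resolved enzyme activity folds
#'
#' @param time time grid (min).
#' @param fold numeric matrix, one column per enzyme, fold >= 1.
#' @return an object of class `activity_fold`.
#' @export
activity_fold <- function(time, fold) {
  fold <- as.matrix(fold)
  stopifnot(length(time) == nrow(fold), !is.null(colnames(fold)))
  if (any(fold < 1 - 1e-9))
    stop("activity_fold: folds must be >= 1", call. = FALSE)
  structure(list(time = as.numeric(time), fold = fold),
            class = "activity_fold")
}

#' Extend a CYP3A4 activity fold to other CYP enzymes
#'
#' Induction of weaker-responding CYPs is modelled by increment scaling:
#' `fold_e(t) = 1 + ratio_e * (fold_3A4(t) - 1)`, which preserves
#' fold >= 1 and interprets the ratios as relative induction strengths.
#'
#' @param fold3a4 an [activity_fold()] containing a `CYP3A4` column.
#' @param ratios named numeric vector of induction ratios in \[0, 1\];
#'   defaults to [default_induction_ratios()].
#' @return an `activity_fold` covering CYP3A4 and all ratio enzymes.
#' @export
extend_to_other_cyps <- function(fold3a4, ratios = default_induction_ratios()) {
  stopifnot(inherits(fold3a4, "activity_fold"))
  if (!"CYP3A4" %in% colnames(fold3a4$fold))
    stop("extend_to_other_cyps: input lacks a CYP3A4 fold", call. = FALSE)
  if (is.null(names(ratios)) || any(!nzchar(names(ratios))))
    stop("extend_to_other_cyps: ratios must be a named vector", call. = FALSE)
  if (any(ratios < 0 | ratios > 1))
    stop("extend_to_other_cyps: ratios must lie in [0, 1]", call. = FALSE)
  f3 <- fold3a4$fold[, "CYP3A4"]
  ext <- vapply(ratios, function(r) 1 + r * (f3 - 1),
                numeric(length(f3)))
  if (is.null(dim(ext))) ext <- matrix(ext, nrow = 1,
                                       dimnames = list(NULL, names(ratios)))
  all_fold <- cbind(CYP3A4 = f3, ext)
  activity_fold(fold3a4$time, all_fold)
}
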