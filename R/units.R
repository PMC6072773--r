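#' Unit conversions used throughout the package
#'
#' Internally all amounts are micromoles, all concentrations micromol/L and
#' all times minutes.  Conversion to mass units (ng/ml) or hours happens only
#' at the reporting boundary, via the molecular weight of the compound.
#'
#' @param mg mass in milligrams.
#' @param mw molecular weight in g/mol.
#' @name units
NULL

#' @rdname units
#' @export
mg_to_umol <- function(mg, mw) {
  stopifnot(mw > 0)
  mg * 1000 / mw
}

#' @rdname units
#' @param umol amount in micromoles.
#' @export
umol_to_mg <- function(umol, mw) {
  stopifnot(mw > 0)
  umol * mw / 1000
}

#' @rdname units
#' @param umol_l concentration in micromol/L.
#' @export
umol_l_to_ng_ml <- function(umol_l, mw) {
  stopifnot(mw > 0)
  umol_l * mw            # umol/L * g/mol == ug/L == ng/ml
}

#' @rdname units
#' @param ng_ml concentration in ng/ml.
#' @export
ng_ml_to_umol_l <- function(ng_ml, mw) {
  stopifnot(mw > 0)
  ng_ml / mw
}

min_to_h <- function(min) min / 60
h_to_min <- function(h) h * 60
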