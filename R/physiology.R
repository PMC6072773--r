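#' Physiology objects for the reduced whole-body PBPK layout
#'
#' A `physiology` describes the compartment graph the PBPK engine integrates
#' over: compartment volumes (L), plasma flows (L/min), the hematocrit, and
#' per-compartment relative enzyme abundances (liver-normalised).  Two
#' layouts are supported:
#'
#' * `"whole_body"` — the reduced adult layout: arterial plasma, venous
#'   plasma, venous blood cells, gut lumen, gut wall, liver split into
#'   vascular / interstitial / intracellular sub-compartments, kidney and a
#'   lumped periphery.  Oral doses enter the gut lumen and reach the liver
#'   via the portal flow, so first-pass extraction is structural.
#' * `"one_compartment"` — a single central volume plus a gut lumen; used
#'   for closed-form checks and synthetic-data calibration exercises.
#'
#' @param body_weight body weight in kg.
#' @param hematocrit haematocrit as a fraction in (0, 1).
#' @param compartments data.frame with columns `name`, `volume` (L),
#'   `flow` (plasma L/min; `NA` for non-perfused pools), `organ`,
#'   `fraction` (fractional volume of the parent organ).
#' @param enzyme_expression named list: enzyme -> named numeric vector of
#'   per-compartment relative abundances (liver intracellular = 1).
#' @param layout `"whole_body"` or `"one_compartment"`.
#' @return an object of class `physiology`.
#' @export
physiology <- function(compartments, body_weight = 73, hematocrit = 0.45,
                       enzyme_expression = list(),
                       layout = c("whole_body", "one_compartment")) {
  layout <- match.arg(layout)
  stopifnot(is.data.frame(compartments),
            all(c("name", "volume", "flow", "organ", "fraction") %in%
                  names(compartments)))
  obj <- structure(
    list(body_weight = body_weight, hematocrit = hematocrit,
         compartments = compartments,
         enzyme_expression = enzyme_expression, layout = layout),
    class = "physiology")
  validate_physiology(obj)
  obj
}

#' Validate a physiology object
#'
#' Checks strict positivity of volumes and flows, hematocrit in (0,1), and
#' that fractional sub-compartment volumes sum to one within each organ.
#'
#' @param phys a `physiology`.
#' @return `phys`, invisibly; errors describe the offending field.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "physiology"))
  cmp <- phys$compartments
  if (phys$body_weight <= 0)
    stop("physiology: body_weight must be > 0", call. = FALSE)
  if (phys$hematocrit <= 0 || phys$hematocrit >= 1)
    stop("physiology: hematocrit must lie in (0, 1)", call. = FALSE)
  if (any(cmp$volume <= 0))
    stop("physiology: non-positive volume for compartment(s): ",
         paste(cmp$name[cmp$volume <= 0], collapse = ", "), call. = FALSE)
  fl <- cmp$flow[!is.na(cmp$flow)]
  if (any(fl <= 0))
    stop("physiology: non-positive flow", call. = FALSE)
  for (org in unique(cmp$organ)) {
    fr <- cmp$fraction[cmp$organ == org]
    if (abs(sum(fr) - 1) > 1e-6)
      stop("physiology: sub-compartment fractions of organ '", org,
           "' sum to ", sum(fr), ", expected 1", call. = FALSE)
  }
  for (enz in names(phys$enzyme_expression)) {
    ex <- phys$enzyme_expression[[enz]]
    bad <- setdiff(names(ex), cmp$name)
    if (length(bad))
      stop("physiology: enzyme_expression for ", enz,
           " references unknown compartment(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(ex < 0))
      stop("physiology: negative enzyme expression for ", enz, call. = FALSE)
  }
  invisible(phys)
}

#' Default reduced whole-body physiology (73 kg adult)
#'
#' Volumes and plasma flows are rounded textbook values for a 73 kg adult
#' male; plasma flows are blood flows scaled by (1 - hematocrit).  CYP and
#' UGT expression is liver-dominated with a small CYP3A4/UGT2B7 contribution
#' in the gut wall; enzymes default to zero expression elsewhere.
#'
#' @param enzymes character vector of enzyme names to register expression
#'   for (all get the same liver/gut-wall pattern).
#' @return a `physiology` with layout `"whole_body"`.
#' @export
default_physiology <- function(enzymes = c("CYP3A4", "CYP2C9", "CYP2J2",
                                           "CYP1A2", "UGT2B7", "UGT1A6",
                                           "ADH", "esterase")) {
  cmp <- data.frame(
    name = c("arterial_plasma", "venous_plasma", "venous_cells",
             "gut_lumen", "gut_wall",
             "liver_vascular", "liver_interstitial", "liver_intracellular",
             "kidney", "periphery"),
    volume = c(1.2, 2.2, 1.8,
               1.0, 1.1,
               0.45, 0.50, 0.85,
               0.31, 35.0),
    flow = c(NA, NA, NA,
             NA, 0.90,
             0.35, NA, NA,
             0.66, 1.20),
    organ = c("arterial_blood", "venous_blood", "venous_blood",
              "gut", "gut",
              "liver", "liver", "liver",
              "kidney", "periphery"),
    fraction = c(1, 0.55, 0.45,
                 0.476, 0.524,
                 0.25, 0.278, 0.472,
                 1, 1),
    stringsAsFactors = FALSE)
  gut_frac <- c(CYP3A4 = 0.10, UGT2B7 = 0.05)
  expr <- lapply(enzymes, function(e) {
    v <- c(liver_intracellular = 1)
    if (e %in% names(gut_frac)) v <- c(v, gut_wall = unname(gut_frac[e]))
    v
  })
  names(expr) <- enzymes
  physiology(cmp, body_weight = 73, hematocrit = 0.45,
             enzyme_expression = expr, layout = "whole_body")
}

#' Minimal one-compartment physiology
#'
#' A single well-stirred central volume plus a gut lumen for oral dosing.
#' Enzyme expression: all enzymes expressed in `central` with abundance 1.
#'
#' @param volume central volume of distribution (L).
#' @param enzymes enzymes expressed in the central compartment.
#' @return a `physiology` with layout `"one_compartment"`.
#' @export
one_compartment_physiology <- function(volume = 10, enzymes = "CL") {
  cmp <- data.frame(
    name = c("central", "gut_lumen"),
    volume = c(volume, 1.0),
    flow = c(NA, NA),
    organ = c("central", "gut"),
    fraction = c(1, 1),
    stringsAsFactors = FALSE)
  expr <- lapply(enzymes, function(e) c(central = 1))
  names(expr) <- enzymes
  physiology(cmp, body_weight = 73, hematocrit = 0.45,
             enzyme_expression = expr, layout = "one_compartment")
}
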