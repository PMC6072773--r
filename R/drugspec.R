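#' Drug specifications and ADME processes
#'
#' A `drug_spec` bundles the physicochemical and kinetic information the
#' PBPK engine needs for one compound: molecular weight, plasma fraction
#' unbound, tissue partition coefficients, an oral-absorption block, the
#' list of ADME processes acting on it, and (recursively) the specs of its
#' metabolites.
#'
#' @param name compound name (unique within a model).
#' @param molecular_weight g/mol, > 0.
#' @param fraction_unbound unbound fraction in plasma, in (0, 1].
#' @param partition_coefficients named numeric vector compartment -> Kp
#'   (plasma-referenced, dimensionless).  Missing compartments default to 1.
#' @param absorption list with `ka` (1/min), `lag` (min) and `formulation`
#'   (`"dissolved"`); `NULL` for compounds never dosed orally.
#' @param processes list of [adme_process()] objects.
#' @param metabolites list of `drug_spec` objects (recursive, acyclic).
#' @param fraction_unbound_cells unbound fraction inside blood cells;
#'   defaults to the plasma fraction unbound.
#' @return an object of class `drug_spec`.
#' @export
drug_spec <- function(name, molecular_weight, fraction_unbound,
                      partition_coefficients = numeric(),
                      absorption = NULL, processes = list(),
                      metabolites = list(),
                      fraction_unbound_cells = fraction_unbound) {
  obj <- structure(
    list(name = name, molecular_weight = molecular_weight,
         fraction_unbound = fraction_unbound,
         fraction_unbound_cells = fraction_unbound_cells,
         partition_coefficients = partition_coefficients,
         absorption = absorption, processes = processes,
         metabolites = metabolites),
    class = "drug_spec")
  validate_drug_spec(obj)
  obj
}

#' ADME process descriptor
#'
#' @param kind one of `"metabolism"`, `"transport_influx"`,
#'   `"transport_efflux"`, `"clearance_renal"`, `"clearance_hepatic"`,
#'   `"clearance_biliary"`.
#' @param site compartment the process acts in.
#' @param enzyme enzyme or transporter name (metabolism/transport); scales
#'   with the physiology's per-compartment expression of that enzyme and
#'   with any induction fold applied to it.
#' @param kcat catalytic rate (1/min) for metabolism; multiplied by
#'   `enzyme_scale` (abundance, umol) to give a site Vmax in umol/min.
#' @param enzyme_scale abundance scaling factor for metabolism (so that
#'   `kcat * enzyme_scale` is the liver-normalised Vmax in umol/min).
#' @param km Michaelis constant (umol/L, unbound) for metabolism.
#' @param rate first-order rate constant (1/min) for clearances and
#'   transport.
#' @param product name of the metabolite formed (metabolism), or `NULL`
#'   for terminal metabolism (moles leave the tracked system).
#' @param to destination compartment for transport processes.
#' @return an object of class `adme_process`.
#' @export
adme_process <- function(kind, site, enzyme = NULL,
                         kcat = NULL, enzyme_scale = 1, km = NULL,
                         rate = NULL, product = NULL, to = NULL) {
  kinds <- c("metabolism", "transport_influx", "transport_efflux",
             "clearance_renal", "clearance_hepatic", "clearance_biliary")
  if (!kind %in% kinds)
    stop("adme_process: unknown kind '", kind, "'", call. = FALSE)
  if (kind == "metabolism") {
    if (is.null(enzyme) || is.null(kcat) || is.null(km))
      stop("adme_process: metabolism needs enzyme, kcat and km", call. = FALSE)
    if (kcat < 0 || km <= 0 || enzyme_scale < 0)
      stop("adme_process: metabolism kinetics must be non-negative (km > 0)",
           call. = FALSE)
  } else {
    if (is.null(rate) || rate < 0)
      stop("adme_process: ", kind, " needs a non-negative first-order rate",
           call. = FALSE)
    if (kind %in% c("transport_influx", "transport_efflux") && is.null(to))
      stop("adme_process: transport needs a destination compartment ('to')",
           call. = FALSE)
  }
  structure(list(kind = kind, site = site, enzyme = enzyme, kcat = kcat,
                 enzyme_scale = enzyme_scale, km = km, rate = rate,
                 product = product, to = to),
            class = "adme_process")
}

#' Validate a drug specification (recursively)
#'
#' @param drug a `drug_spec`.
#' @return `drug`, invisibly.
#' @export
validate_drug_spec <- function(drug) {
  stopifnot(inherits(drug, "drug_spec"))
  if (drug$molecular_weight <= 0)
    stop("drug_spec '", drug$name, "': molecular_weight must be > 0",
         call. = FALSE)
  for (f in c("fraction_unbound", "fraction_unbound_cells")) {
    v <- drug[[f]]
    if (v <= 0 || v > 1)
      stop("drug_spec '", drug$name, "': ", f, " must lie in (0, 1]",
           call. = FALSE)
  }
  if (!is.null(drug$absorption)) {
    ab <- drug$absorption
    if (is.null(ab$ka) || ab$ka <= 0)
      stop("drug_spec '", drug$name, "': absorption$ka must be > 0",
           call. = FALSE)
    if (!is.null(ab$lag) && ab$lag < 0)
      stop("drug_spec '", drug$name, "': absorption$lag must be >= 0",
           call. = FALSE)
    if (!identical(ab$formulation %||% "dissolved", "dissolved"))
      stop("drug_spec '", drug$name,
           "': only the dissolved formulation is supported", call. = FALSE)
  }
  met_names <- vapply(drug$metabolites, function(m) m$name, character(1))
  prods <- unlist(lapply(drug$processes, function(p) p$product))
  bad <- setdiff(prods, met_names)
  if (length(bad))
    stop("drug_spec '", drug$name, "': metabolism product(s) ",
         paste(bad, collapse = ", "), " not declared as metabolites",
         call. = FALSE)
  for (m in drug$metabolites) validate_drug_spec(m)
  # acyclicity: a compound name may not reappear below itself
  check_cycle <- function(d, seen) {
    if (d$name %in% seen)
      stop("drug_spec: metabolite graph contains a cycle through '",
           d$name, "'", call. = FALSE)
    for (m in d$metabolites) check_cycle(m, c(seen, d$name))
  }
  check_cycle(drug, character())
  invisible(drug)
}

#' Flatten a drug spec into its list of compounds (parent first)
#'
#' @param drug a `drug_spec`.
#' @return named list of `drug_spec` objects, depth-first, parent first.
#' @export
flatten_compounds <- function(drug) {
  out <- list(drug)
  for (m in drug$metabolites) out <- c(out, flatten_compounds(m))
  names(out) <- vapply(out, function(d) d$name, character(1))
  if (anyDuplicated(names(out)))
    stop("drug_spec: duplicate compound name in metabolite tree", call. = FALSE)
  out
}

#' Oral or intravenous dose event
#'
#' @param route `"oral"` or `"intravenous"`.
#' @param amount dose in mg (> 0).
#' @param time clock time of administration (min).
#' @param repeat_interval optional re-dosing interval (min, > 0).
#' @param repeat_count number of administrations (1 = single dose).
#' @return an object of class `dose_event`.
#' @export
dose_event <- function(route = c("oral", "intravenous"), amount, time = 0,
                       repeat_interval = NULL, repeat_count = 1) {
  route <- match.arg(route)
  if (amount <= 0) stop("dose_event: amount must be > 0", call. = FALSE)
  if (!is.null(repeat_interval) && repeat_interval <= 0)
    stop("dose_event: repeat interval must be > 0", call. = FALSE)
  if (repeat_count > 1 && is.null(repeat_interval))
    stop("dose_event: repeat_count > 1 requires repeat_interval", call. = FALSE)
  structure(list(route = route, amount = amount, time = time,
                 repeat_interval = repeat_interval,
                 repeat_count = repeat_count),
            class = "dose_event")
}

# expand repeats into a data.frame of single administrations
expand_doses <- function(doses) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  rows <- lapply(doses, function(d) {
    times <- d$time + (seq_len(d$repeat_count) - 1) *
      (d$repeat_interval %||% 0)
    data.frame(route = d$route, amount = d$amount, time = times,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
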