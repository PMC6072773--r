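#' Configuration and result I/O
#'
#' Drugs, physiologies, networks and scenarios are configured as YAML
#' files; the packaged set lives under `inst/extdata/`.  Profiles and
#' metrics are exported as tidy CSV (UTF-8, '.' decimal, header row) and
#' JSON summaries.
#'
#' @name aaqsp-io
NULL

extdata_path <- function(...) {
  p <- system.file("extdata", ..., package = "aaqsp")
  if (identical(p, "")) {
    # during development (package not installed) fall back to source tree
    p <- file.path("inst", "extdata", ...)
  }
  p
}

#' Load a packaged (or external) drug configuration
#'
#' @param name packaged drug name (`"diclofenac"`, `"celecoxib"`,
#'   `"zileuton"`, `"licofelone"`, `"rifampicin"`) or a path to a YAML
#'   file following the same schema.
#' @return a list with elements `spec` (a [drug_spec()]), `abbreviation`,
#'   `therapeutic_dose_mg`, and `targets` (data.frame enzyme/ki).
#' @export
load_drug <- function(name) {
  path <- if (file.exists(name)) name else
    extdata_path("drugs", paste0(name, ".yaml"))
  if (!file.exists(path))
    stop("load_drug: no packaged drug or file '", name, "'", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  parse_drug_config(cfg, path)
}

parse_drug_config <- function(cfg, path = "<config>") {
  req <- c("name", "molecular_weight", "fraction_unbound")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("drug config ", path, ": missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  spec <- drug_spec_from_list(cfg)
  targets <- NULL
  if (!is.null(cfg$targets)) {
    targets <- do.call(rbind, lapply(cfg$targets, function(tg)
      data.frame(enzyme = tg$enzyme, ki = tg$ki, stringsAsFactors = FALSE)))
    if (any(targets$ki <= 0))
      stop("drug config ", path, ": targets.ki must be > 0", call. = FALSE)
  }
  list(spec = spec, abbreviation = cfg$abbreviation %||% cfg$name,
       therapeutic_dose_mg = cfg$therapeutic_dose_mg,
       targets = targets)
}

drug_spec_from_list <- function(cfg) {
  procs <- lapply(cfg$processes %||% list(), function(p)
    adme_process(kind = p$kind, site = p$site, enzyme = p$enzyme,
                 kcat = p$kcat, enzyme_scale = p$enzyme_scale %||% 1,
                 km = p$km, rate = p$rate, product = p$product, to = p$to))
  mets <- lapply(cfg$metabolites %||% list(), drug_spec_from_list)
  pc <- unlist(cfg$partition_coefficients %||% list())
  drug_spec(name = cfg$name,
            molecular_weight = cfg$molecular_weight,
            fraction_unbound = cfg$fraction_unbound,
            fraction_unbound_cells = cfg$fraction_unbound_cells %||%
              cfg$fraction_unbound,
            partition_coefficients = if (length(pc)) pc else numeric(),
            absorption = cfg$absorption,
            processes = procs, metabolites = mets)
}

#' Load a network model from the packaged surrogate or a config/SBML file
#'
#' @param source `"surrogate"`, a path to a network YAML, or
#'   `"sbml:<path>"` / a path ending in `.xml`/`.sbml` for SBML import.
#' @return a [network_model()].
#' @export
load_network <- function(source = "surrogate") {
  if (identical(source, "surrogate")) return(surrogate_network())
  if (startsWith(source, "sbml:"))
    return(read_sbml_network(sub("^sbml:", "", source)))
  if (grepl("\\.(xml|sbml)$", source))
    return(read_sbml_network(source))
  cfg <- yaml::read_yaml(source)
  species <- do.call(rbind, lapply(cfg$species, function(s)
    data.frame(name = s$name, initial = s$initial,
               boundary = isTRUE(s$boundary), stringsAsFactors = FALSE)))
  reactions <- lapply(cfg$reactions, function(r)
    mm_reaction(r$name, r$substrate, r$product, r$enzyme, r$vmax, r$km))
  feedback <- lapply(cfg$feedback %||% list(), function(fb)
    list(regulator = fb$regulator, target = fb$target, sign = fb$sign,
         strength = fb$strength, k_half = fb$k_half))
  network_model(species, reactions, feedback,
                provenance = cfg$provenance %||% "packaged_surrogate")
}

#' Validate a configuration file
#'
#' Detects the config kind (drug, scenario or network YAML) and runs the
#' corresponding validators.  Problems are returned (not raised) so a CLI
#' can report them with field paths.
#'
#' @param path YAML file path.
#' @return character vector of problems; empty if the config is valid.
#' @export
validate_config <- function(path) {
  cfg <- try(yaml::read_yaml(path), silent = TRUE)
  if (inherits(cfg, "try-error"))
    return(paste0(path, ": not parseable YAML"))
  probs <- character()
  kind <- if (!is.null(cfg$id) && !is.null(cfg$drugs)) "scenario"
    else if (!is.null(cfg$species)) "network"
    else if (!is.null(cfg$molecular_weight)) "drug"
    else return(paste0(path, ": unrecognised config kind"))
  res <- try(switch(kind,
                    drug = parse_drug_config(cfg, path),
                    network = load_network(path),
                    scenario = parse_scenario_config(cfg, path)),
             silent = TRUE)
  if (inherits(res, "try-error"))
    probs <- c(probs, conditionMessage(attr(res, "condition")))
  probs
}

#' Export a tidy profile CSV
#' @param profile a `profile_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profile, path) {
  utils::write.csv(profile_df(profile), path, row.names = FALSE)
  invisible(path)
}

#' Export an activity-fold CSV (`time_min`, `enzyme`, `fold`)
#' @param folds an [activity_fold()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_folds_csv <- function(folds, path) {
  df <- do.call(rbind, lapply(colnames(folds$fold), function(enz)
    data.frame(time_min = folds$time, enzyme = enz,
               fold = folds$fold[, enz], stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
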