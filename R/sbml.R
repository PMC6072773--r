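#' SBML import and export for network models
#'
#' A focused SBML Level 3 Version 1 subset is supported: species with
#' initial concentrations (and `boundaryCondition`), and reactions with a
#' single reactant, at most one product, and an explicit irreversible
#' Michaelis-Menten kinetic law `Vmax * S / (Km + S)` carried as local
#' parameters `Vmax` and `Km`.  Any other kinetic law raises an
#' unsupported-construct error quoting the law.  Feedback edges and the
#' enzyme labels (which SBML core has no slot for) travel in an
#' `annotation` block under the package's namespace, so a network
#' round-trips losslessly through [write_sbml_network()] and
#' [read_sbml_network()].
#'
#' @name aaqsp-sbml
NULL

AAQSP_NS <- "https://aaqsp.r-pkg/ns"
SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"

#' Export a network model to SBML L3V1
#'
#' @param net a [network_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml_network <- function(net, path) {
  validate_network(net)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:aaqsp="%s" level="3" version="1">',
            SBML_NS, AAQSP_NS),
    '  <model id="aa_network">',
    '    <listOfCompartments>',
    '      <compartment id="cell" size="1" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="cell" initialConcentration="%.17g" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>',
      sbml_id(s$name), s$initial, tolower(as.character(s$boundary))))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfReactions>')
  for (r in net$reactions) {
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="false">', sbml_id(r$name)))
    lines <- c(lines, sprintf(
      '        <annotation><aaqsp:enzyme xmlns:aaqsp="%s">%s</aaqsp:enzyme></annotation>',
      AAQSP_NS, esc(r$enzyme)))
    lines <- c(lines,
      '        <listOfReactants>',
      sprintf('          <speciesReference species="%s" stoichiometry="1" constant="true"/>',
              sbml_id(r$substrate)),
      '        </listOfReactants>')
    if (!is.null(r$product)) {
      lines <- c(lines,
        '        <listOfProducts>',
        sprintf('          <speciesReference species="%s" stoichiometry="1" constant="true"/>',
                sbml_id(r$product)),
        '        </listOfProducts>')
    }
    lines <- c(lines,
      '        <kineticLaw>',
      '          <math xmlns="http://www.w3.org/1998/Math/MathML">',
      '            <apply><divide/>',
      sprintf('              <apply><times/><ci>Vmax</ci><ci>%s</ci></apply>',
              sbml_id(r$substrate)),
      sprintf('              <apply><plus/><ci>Km</ci><ci>%s</ci></apply>',
              sbml_id(r$substrate)),
      '            </apply>',
      '          </math>',
      '          <listOfLocalParameters>',
      sprintf('            <localParameter id="Vmax" value="%.17g"/>', r$vmax),
      sprintf('            <localParameter id="Km" value="%.17g"/>', r$km),
      '          </listOfLocalParameters>',
      '        </kineticLaw>',
      '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (length(net$feedback)) {
    fb_lines <- vapply(net$feedback, function(fb) sprintf(
      '        <aaqsp:feedback regulator="%s" target="%s" sign="%d" strength="%.17g" k_half="%.17g"/>',
      sbml_id(fb$regulator), sbml_id(fb$target), fb$sign, fb$strength,
      fb$k_half), character(1))
    lines <- c(lines,
      '    <annotation>',
      sprintf('      <aaqsp:feedbackEdges xmlns:aaqsp="%s">', AAQSP_NS),
      fb_lines,
      '      </aaqsp:feedbackEdges>',
      '    </annotation>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

# SBML SIds cannot contain '-'; encode and decode reversibly
sbml_id <- function(x) gsub("-", "__", x)
sbml_unid <- function(x) gsub("__", "-", x)

#' Import a network model from an SBML file
#'
#' @param path SBML file.
#' @return a [network_model()] with provenance `"sbml_import"`.
#' @export
read_sbml_network <- function(path) {
  if (!file.exists(path))
    stop("read_sbml_network: file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, m = "http://www.w3.org/1998/Math/MathML",
          a = AAQSP_NS)

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp_nodes) == 0)
    stop("read_sbml_network: no species found (SBML L3V1 expected)",
         call. = FALSE)
  species <- data.frame(
    name = sbml_unid(xml2::xml_attr(sp_nodes, "id")),
    initial = as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")),
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)
  species$boundary[is.na(species$boundary)] <- FALSE
  if (anyNA(species$initial))
    stop("read_sbml_network: species without initialConcentration are not ",
         "supported", call. = FALSE)

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx_nodes, function(rx) {
    rid <- sbml_unid(xml2::xml_attr(rx, "id"))
    reac <- xml2::xml_find_all(rx,
      "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rx,
      "./s:listOfProducts/s:speciesReference", ns)
    if (length(reac) != 1 || length(prod) > 1)
      stop("read_sbml_network: reaction '", rid, "' must have exactly one ",
           "reactant and at most one product", call. = FALSE)
    substrate <- sbml_unid(xml2::xml_attr(reac, "species"))
    product <- if (length(prod)) sbml_unid(xml2::xml_attr(prod, "species"))
      else NULL
    kl <- xml2::xml_find_first(rx, "./s:kineticLaw", ns)
    if (inherits(kl, "xml_missing"))
      stop("read_sbml_network: reaction '", rid, "' has no kinetic law",
           call. = FALSE)
    pars <- xml2::xml_find_all(kl,
      ".//s:localParameter | .//s:parameter", ns)
    pv <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
    math <- xml2::xml_find_first(kl, "./m:math", ns)
    if (!is_mm_math(math, sbml_id(substrate), ns))
      stop("read_sbml_network: unsupported kinetic law in reaction '", rid,
           "': ", gsub("\\s+", " ", as.character(math)),
           "; only irreversible Michaelis-Menten laws Vmax*S/(Km+S) with ",
           "local parameters Vmax and Km are supported", call. = FALSE)
    if (!all(c("Vmax", "Km") %in% names(pv)))
      stop("read_sbml_network: reaction '", rid,
           "' lacks local parameters Vmax/Km", call. = FALSE)
    enz <- xml2::xml_find_first(rx, "./s:annotation/a:enzyme", ns)
    enzyme <- if (inherits(enz, "xml_missing")) rid else xml2::xml_text(enz)
    mm_reaction(rid, substrate, product, enzyme,
                vmax = pv[["Vmax"]], km = pv[["Km"]])
  })

  fb_nodes <- xml2::xml_find_all(doc,
    ".//s:model/s:annotation/a:feedbackEdges/a:feedback", ns)
  feedback <- lapply(fb_nodes, function(fb) list(
    regulator = sbml_unid(xml2::xml_attr(fb, "regulator")),
    target = sbml_unid(xml2::xml_attr(fb, "target")),
    sign = as.integer(xml2::xml_attr(fb, "sign")),
    strength = as.numeric(xml2::xml_attr(fb, "strength")),
    k_half = as.numeric(xml2::xml_attr(fb, "k_half"))))

  network_model(species, reactions, feedback, provenance = "sbml_import")
}

# recognise the canonical irreversible MM MathML pattern
# divide( times(Vmax, S), plus(Km, S) )  (ci order within times/plus free)
is_mm_math <- function(math, sid, ns) {
  if (inherits(math, "xml_missing")) return(FALSE)
  top <- xml2::xml_find_first(math, "./m:apply", ns)
  if (inherits(top, "xml_missing")) return(FALSE)
  kids <- xml2::xml_children(top)
  if (length(kids) != 3) return(FALSE)
  if (xml2::xml_name(kids[[1]]) != "divide") return(FALSE)
  get_cis <- function(node, op) {
    if (xml2::xml_name(node) != "apply") return(NULL)
    ch <- xml2::xml_children(node)
    if (length(ch) != 3 || xml2::xml_name(ch[[1]]) != op) return(NULL)
    if (any(vapply(ch[2:3], xml2::xml_name, "") != "ci")) return(NULL)
    trimws(vapply(ch[2:3], xml2::xml_text, ""))
  }
  num <- get_cis(kids[[2]], "times")
  den <- get_cis(kids[[3]], "plus")
  if (is.null(num) || is.null(den)) return(FALSE)
  setequal(num, c("Vmax", sid)) && setequal(den, c("Km", sid))
}
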