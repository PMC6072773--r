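#' Load a physiology from the packaged set or a YAML file
#'
#' @param name packaged physiology name (`"human_73kg"`) or a YAML path.
#' @return a [physiology()].
#' @export
load_physiology <- function(name = "human_73kg") {
  path <- if (file.exists(name)) name else
    extdata_path("physiology", paste0(name, ".yaml"))
  if (!file.exists(path))
    stop("load_physiology: no packaged physiology or file '", name, "'",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cmp <- do.call(rbind, lapply(cfg$compartments, function(r)
    data.frame(name = r$name, volume = r$volume,
               flow = if (is.null(r$flow)) NA_real_ else r$flow,
               organ = r$organ, fraction = r$fraction,
               stringsAsFactors = FALSE)))
  physiology(cmp, body_weight = cfg$body_weight,
             hematocrit = cfg$hematocrit,
             enzyme_expression = lapply(cfg$enzyme_expression, unlist),
             layout = cfg$layout %||% "whole_body")
}
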