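# Shared YAML/JSON configuration for the analysis drivers: a `theory:` block
# (K, n, S, dLV, dLA, dN, sigma, epsilon) plus free-form blocks for the
# generators.

#' Read an analysis configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`, requires the yaml package) or JSON
#' configuration and materializes the `theory` block into a
#' [stimulus_spec()] and [code_params()] pair; other blocks are returned
#' as-is.
#'
#' @param path Path to the configuration file.
#' @return A list; if a `theory` block is present it gains `spec` and
#'   `params` elements.
#' @export
read_bindgeom_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$theory)) {
    th <- cfg$theory
    cfg$theory$spec <- stimulus_spec(K = th$K %||% 2, n = th$n %||% 2,
                                     S = th$S %||% 2)
    cfg$theory$params <- code_params(dLV = th$dLV %||% 1,
                                     dLA = th$dLA %||% th$dLV %||% 1,
                                     dN = th$dN %||% 0,
                                     sigma = th$sigma %||% 0.5,
                                     epsilon = th$epsilon %||% 0)
  }
  cfg
}
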