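#' Read simulator parameters from a YAML or JSON configuration file
#'
#' A file with a `group_sizes` field is interpreted as a
#' [cohort_sim_params()] configuration; any other mapping as a
#' [beat_model_params()] configuration.  A `backflow_probs` list of five
#' 3-vectors is assembled row-wise into the 5x3 probability matrix.
#'
#' @param path Path to the YAML (or JSON, which YAML parses) file.
#' @return A `beat_model_params` or `cohort_sim_params` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("Configuration file must contain a mapping.")
  if ("group_sizes" %in% names(cfg)) {
    if (!is.null(cfg$backflow_probs)) {
      cfg$backflow_probs <- do.call(rbind, lapply(cfg$backflow_probs, as.numeric))
    }
    for (nm in c("group_sizes", "ica_dbp_mean", "ica_dbp_sd",
                 "ica_pp_mean", "ica_pp_sd")) {
      if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.numeric(cfg[[nm]])
    }
    do.call(cohort_sim_params, cfg)
  } else {
    do.call(beat_model_params, cfg)
  }
}

#' Write simulator parameters to a YAML configuration file
#'
#' @param params A [beat_model_params()] or [cohort_sim_params()] object.
#' @param path Output path.
#' @return `params`, invisibly.
#' @export
write_sim_config <- function(params, path) {
  stopifnot(inherits(params, c("beat_model_params", "cohort_sim_params")))
  cfg <- unclass(params)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  if (!is.null(cfg$backflow_probs)) {
    cfg$backflow_probs <- lapply(seq_len(nrow(cfg$backflow_probs)),
                                 function(i) as.numeric(cfg$backflow_probs[i, ]))
  }
  yaml::write_yaml(cfg, path)
  invisible(params)
}
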