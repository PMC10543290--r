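# Simulation configs can be read from JSON (always) or YAML (when the yaml
# package is available); ground truth is serialized as JSON.

#' Read a simulation configuration from JSON or YAML
#'
#' The file holds the arguments of [eeg_sim_config()] or [mea_sim_config()];
#' a top-level `kind` field ("eeg" or "mea") selects the constructor, which
#' validates the values.
#'
#' @param path .json, .yaml or .yml file.
#' @return An `eeg_sim_config` or `mea_sim_config`.
#' @export
read_sim_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  kind <- lst$kind %||% stop("config needs a 'kind' field: 'eeg' or 'mea'")
  lst$kind <- NULL
  if (!is.null(lst$state_transition_matrix))
    lst$state_transition_matrix <- matrix(unlist(lst$state_transition_matrix),
                                          4, 4, byrow = TRUE)
  if (!is.null(lst$state_profile))
    lst$state_profile <- data.frame(lst$state_profile,
                                    row.names = SLEEP_STATES)
  switch(kind,
         eeg = do.call(eeg_sim_config, lst),
         mea = do.call(mea_sim_config, lst),
         stop("unknown config kind: ", kind))
}

#' Serialize simulation ground truth to JSON
#'
#' @param truth the `truth` element returned by [simulate_eeg()] or
#'   [simulate_raster()].
#' @param path output .json path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  if (inherits(out$hypnogram, "hypnogram"))
    out$hypnogram <- list(epoch_len_s = out$hypnogram$epoch_len_s,
                          labels = out$hypnogram$labels)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
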