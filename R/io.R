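#' Read and write the pipeline's tables and configuration
#'
#' Plain-text interchange: tracks and incidents as CSV (with a comment line
#' declaring the configuration hash when one is supplied), configuration as
#' YAML, simulation truth and result summaries as JSON.
#'
#' @param x object to write.
#' @param path file path.
#' @param hash optional configuration hash recorded in a leading comment.
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @name shimmer_io
NULL

#' @rdname shimmer_io
#' @export
write_table_csv <- function(x, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname shimmer_io
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' @rdname shimmer_io
#' @export
write_config_yaml <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname shimmer_io
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(shimmer_config, raw[names(raw) %in% names(formals(shimmer_config))])
}

#' @rdname shimmer_io
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x[c("incidents", "dir_true", "empty")], path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Incidents table in the interchange layout
#'
#' @param incidents annotated incidents from [run_pipeline()].
#' @param fps frame rate used to add onset times in ms.
#' @return data.frame `(agent_id, t0_frame, t0_ms, peak_rel, c_ws, wave_id,
#'   role, trigger_id, dir_trig, dir_wav)`.
#' @export
incidents_table <- function(incidents, fps = 60) {
  data.frame(agent_id = incidents$agent_id,
             t0_frame = incidents$t0,
             t0_ms = incidents$t0 * 1000 / fps,
             peak_rel = incidents$peak_rel,
             c_ws = incidents$c_ws,
             wave_id = incidents$wave_id,
             role = incidents$role,
             trigger_id = incidents$trigger_id,
             dir_trig = incidents$dir_trig,
             dir_wav = incidents$dir_wav)
}
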