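#' Serialize distributions, curves and trajectories
#'
#' Plain-text interchange: probability vectors and information curves are
#' written as CSV (one row per synapse count or time point) with an
#' optional JSON sidecar carrying the metadata (condition, model
#' parameters, reference values) needed to reproduce them.
#'
#' @param p a [synapse_dist] (or probability vector).
#' @param file CSV path.
#' @param meta named list written as `<file>.json`; omit for no sidecar.
#' @return the file path, invisibly.
#' @export
write_distribution <- function(p, file, meta = NULL) {
  check_distribution(p)
  df <- data.frame(S = seq_along(p) - 1L, p = as.numeric(p))
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(meta)) write_sidecar(file, meta)
  invisible(file)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(file) {
  df <- utils::read.csv(file)
  new_synapse_dist(df$p[order(df$S)])
}

#' @param curve an `"mi_curve"` data frame.
#' @rdname write_distribution
#' @export
write_mi_curve <- function(curve, file, meta = NULL) {
  utils::write.csv(curve[, c("time", "mi")], file, row.names = FALSE)
  if (!is.null(meta)) write_sidecar(file, meta)
  invisible(file)
}

#' @param traj matrix of distributions (rows = times) with a `times` vector.
#' @param times time steps matching the rows of `traj`.
#' @rdname write_distribution
#' @export
write_trajectory <- function(traj, times, file, meta = NULL) {
  df <- data.frame(time = times, traj, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(meta)) write_sidecar(file, meta)
  invisible(file)
}

write_sidecar <- function(file, meta) {
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Run manifest for reproducible protocol runs
#'
#' Writes a JSON manifest recording the package version, model parameters,
#' protocol arguments and seeds of a run.
#'
#' @param path output JSON path.
#' @param object a [synapse_model()].
#' @param ... further named entries (protocol, seed, mode, ...).
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, object, ...) {
  meta <- list(package = "synturn",
               version = as.character(utils::packageVersion("synturn")),
               parameters = as.list(coef(object)), ...)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
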