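#' Write a session to disk as CSV + JSON + YAML
#'
#' Serializes a `nirs_session` as three plain-text files in `dir`:
#' `session.csv` (column `time_s` plus one optical-density column per
#' channel x wavelength, full precision), `events.json` (array of trial
#' event objects) and `meta.yaml` (sample rate, channel table and generator
#' settings). Ground-truth annotations are not written; they exist only on
#' the in-memory generator output.
#'
#' @param session A `nirs_session`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "nirs_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$od, file.path(dir, "session.csv"),
                   row.names = FALSE)
  jsonlite::write_json(session$events, file.path(dir, "events.json"),
                       digits = NA, auto_unbox = FALSE)
  em <- session$meta$extinction
  meta <- list(
    sample_rate_hz = session$meta$sample_rate_hz,
    n_trials = session$meta$n_trials,
    cued = session$meta$cued,
    color_scheme = session$meta$color_scheme,
    seed = session$meta$seed,
    channels = as.data.frame(session$channels),
    extinction = list(E = as.vector(t(em$E)),
                      path_length_cm = em$path_length_cm)
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing `session.csv`, `events.json`, `meta.yaml`.
#' @return A `nirs_session` (without ground-truth annotations).
#' @export
read_session <- function(dir) {
  od <- tibble::as_tibble(utils::read.csv(file.path(dir, "session.csv"),
                                          check.names = FALSE))
  events <- tibble::as_tibble(
    jsonlite::fromJSON(file.path(dir, "events.json")))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  ev <- as.vector(unlist(meta$extinction$E))
  em <- extinction_matrix(ev[1], ev[2], ev[3], ev[4],
                          meta$extinction$path_length_cm)
  channels <- tibble::as_tibble(as.data.frame(meta$channels))
  structure(list(
    od = od, events = events, channels = channels,
    meta = list(sample_rate_hz = meta$sample_rate_hz,
                n_trials = meta$n_trials, cued = meta$cued,
                color_scheme = meta$color_scheme, seed = meta$seed,
                extinction = em),
    ground_truth = NULL
  ), class = "nirs_session")
}
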