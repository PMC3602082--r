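.snapshot_version <- 1L

#' Save a full coupled state snapshot
#'
#' Bit-exact persistence of an `em_state` (including the Verlet position
#' history and the fading-memory terms) so that a resumed run continues
#' identically. Snapshots are RDS containers with a format-version header
#' and the configuration hash of the run that produced them.
#'
#' @param state `em_state` (or any package state object)
#' @param path output file
#' @param config_hash optional configuration hash stored for provenance
#' @export
save_snapshot <- function(state, path, config_hash = NULL) {
  obj <- list(format = "cardiomech-snapshot",
              version = .snapshot_version,
              config_hash = config_hash,
              state = state)
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' Load a state snapshot
#'
#' @param path snapshot file
#' @return the stored state
#' @export
load_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("unreadable or truncated snapshot: ", path, " (", conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$format, "cardiomech-snapshot"))
    stop("not a cardiomech snapshot: ", path)
  if (!identical(obj$version, .snapshot_version))
    stop(sprintf(
      "snapshot format version %s; this package reads version %s (re-save the state with the matching package release)",
      obj$version, .snapshot_version))
  obj$state
}
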