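# Run configuration: one YAML document with a parameter block per stage.
# Every run writes the fully resolved config next to its outputs, so the
# defaults in force are always on disk.

#' Default run configuration
#'
#' Nested list with one block per pipeline stage, every default
#' materialized. Unknown keys in a user file are rejected rather than
#' silently ignored.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    log_level = "info",
    synthetic = list(step = 4, label_noise = 0.2, jitter_sigma = 1,
                     n_filaments = 9, radius_smoothing = 20),
    voting = list(window = 8, use_3d_neighbors = FALSE, k = 15, max_iter = 50),
    lattice = list(bandwidth = 4, n_doublets = 9),
    xl = list(fdr_a = 0.01, fdr_b = 0.05, cutoff = 35),
    uexm = list(reference = 250, threshold_frac = 0.5)
  )
}

#' Read and resolve a run configuration
#'
#' Reads YAML, rejects unknown keys at the top level and inside each
#' stage block, and merges the result over [default_config()] so every
#' stage's defaults are materialized.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stopf("read_run_config: no such file: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0)
    stopf("read_run_config: unknown key(s): %s", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad) > 0)
        stopf("read_run_config: unknown key(s) in '%s': %s", k,
              paste(bad, collapse = ", "))
      cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

#' Persist a resolved configuration
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
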