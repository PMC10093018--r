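#' Default pipeline configuration
#'
#' Nested list of per-stage parameter blocks (`simulate`, `enhance`,
#' `augment`, `extract`, `fuse`, `select`, `classify`) plus `seed`,
#' `verbosity` and `output_dir`. Every stage derives its own RNG seed
#' deterministically from the master seed.
#'
#' @return a named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 0L,
    verbosity = 1L,
    output_dir = "mammofuse_run",
    simulate = list(n_per_class = 10L, side = 96L, haze_strength = 0.5,
                    noise_sigma = 0.01),
    enhance = list(patch_size = 15L, omega = 0.95, t_floor = 0.1,
                   airlight_fraction = 0.001, global_gain = 0.5,
                   local_gain = 0.5, local_window = 11L,
                   local_alpha = 0.01, clip_output = TRUE,
                   global_reading = "gain_about_mean"),
    augment = list(include_originals = FALSE),
    extract = list(kind = "filterbank", scales = 2L, orientations = 4L,
                   bins = 8L),
    fuse = list(),
    select = list(pop_size = 20L, max_iters = 50L, a1 = 2, a2 = 1,
                  gp = 0.5, gcp_scale = 0.65, binarize_tau = 0.5,
                  rf_tol = 1e-4, rf_window = 3L,
                  phase_mode = "interleaved",
                  holdout_fraction = 0.3),
    classify = list(roster = c("fine_knn", "linear_svm"))
  ), class = "run_config")
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, checks every key against the default configuration
#' schema (unknown keys are rejected with their full path named), and
#' fills unset values with defaults. An empty file yields the defaults.
#'
#' @param path YAML file path.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user, prefix = "")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a block")
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(full, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Per-stage seeds derived from the master seed
#'
#' @param config a `run_config` (or master seed integer).
#' @return named integer vector of stage seeds.
#' @export
stage_seeds <- function(config) {
  master <- if (is.list(config)) config$seed else config
  stages <- c("simulate", "enhance", "augment", "extract", "fuse",
              "select", "classify", "protocol")
  stats::setNames(vapply(stages, function(s) derive_seed(master, s),
                         integer(1)), stages)
}
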