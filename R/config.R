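# Layered run configuration: documented defaults, optional YAML config
# file, and explicit overrides, with validation of every tolerance and
# threshold.

#' Default run configuration
#'
#' All tunable tolerances and thresholds of the pipeline with their
#' defaults: m/z tolerances (Da), the two-tier library-search thresholds,
#' the analog-search window and thresholds, the ion-form R-squared cutoff,
#' blank-fold and noise-floor filters, the analog frequency cap, and the
#' duplicate-collapse score.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    precursor_tol = 0.02,
    frag_tol = 0.02,
    offset_tol = 0.01,
    xic_tol = 0.01,
    search_min_score = 0.7,
    search_min_peaks = 2,
    accept_min_score = 0.9,
    accept_min_peaks = 5,
    analog_window = 200,
    analog_min_score = 0.8,
    analog_min_peaks = 6,
    r2_threshold = 0.9,
    blank_fold = 3,
    noise_floor = 1e4,
    max_frequency = 0.5,
    dedup_min_score = 0.95,
    cluster_k = 4,
    ontology_level = "pharmacologic_class",
    workdir = ".",
    seed = 1,
    log_level = "info"
  )
}

.validate_config <- function(cfg) {
  pos <- c("precursor_tol", "frag_tol", "offset_tol", "xic_tol",
           "analog_window", "blank_fold")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("config value '", k, "' must be > 0", call. = FALSE)
    }
  }
  unit <- c("search_min_score", "accept_min_score", "analog_min_score",
            "r2_threshold", "max_frequency", "dedup_min_score")
  for (k in unit) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 1) {
      stop("config value '", k, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  cnt <- c("search_min_peaks", "accept_min_peaks", "analog_min_peaks",
           "cluster_k")
  for (k in cnt) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1) {
      stop("config value '", k, "' must be >= 1", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$noise_floor) || cfg$noise_floor < 0) {
    stop("config value 'noise_floor' must be >= 0", call. = FALSE)
  }
  if (!cfg$ontology_level %in% .ontology_levels) {
    stop("config value 'ontology_level' must be one of: ",
         paste(.ontology_levels, collapse = ", "), call. = FALSE)
  }
  cfg
}

#' Resolve the run configuration
#'
#' Merges, in increasing precedence: the package defaults, a YAML config
#' file, and explicit overrides (CLI flags). Unknown keys and out-of-range
#' values raise errors naming the offending key.
#'
#' @param config_file Optional YAML file path.
#' @param overrides Named list of explicit overrides.
#' @param defaults Base configuration.
#' @return Validated configuration list.
#' @export
resolve_config <- function(config_file = NULL, overrides = list(),
                           defaults = default_config()) {
  cfg <- defaults
  apply_layer <- function(cfg, layer, origin) {
    if (is.null(layer)) return(cfg)
    unknown <- setdiff(names(layer), names(defaults))
    if (length(unknown)) {
      stop("unknown config key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg[names(layer)] <- layer
    cfg
  }
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop("config file not found: ", config_file, call. = FALSE)
    }
    cfg <- apply_layer(cfg, yaml::read_yaml(config_file), config_file)
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  .validate_config(cfg)
}
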