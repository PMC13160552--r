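# flat key schema shared by the whole pipeline; each entry: default +
# validation range
.config_schema <- list(
  identity_threshold = list(default = 0.5, lo = 0, hi = 1),
  identity_strict    = list(default = FALSE),
  flank_len          = list(default = 1000, lo = 0, hi = Inf, int = TRUE),
  flank_identity_min = list(default = 0.8, lo = 0, hi = 1),
  e_max              = list(default = 1e-5, lo = 1e-300, hi = Inf),
  seed_length        = list(default = 11, lo = 4, hi = 32, int = TRUE),
  exon2_window       = list(default = 30, lo = 1, hi = Inf, int = TRUE),
  ltr_identity_min   = list(default = 0.7, lo = 0, hi = 1),
  ltr_window         = list(default = 500, lo = 0, hi = Inf, int = TRUE),
  phi_window         = list(default = 100, lo = 1, hi = Inf, int = TRUE),
  phi_permutations   = list(default = 1000, lo = 1, hi = Inf, int = TRUE),
  seed               = list(default = 1, lo = 1, hi = 2^31 - 1, int = TRUE)
)

#' Load and validate a pipeline configuration
#'
#' Reads a flat YAML key/value file, fills in defaults for absent keys,
#' rejects unknown keys and range-checks every value (e.g. identity
#' thresholds must lie in `[0, 1]`). With `path = NULL` the full default
#' set is returned.
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @return a named list of class `run_config` containing every schema key.
#' @export
load_run_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), names(.config_schema))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- lapply(names(.config_schema), function(k) {
    spec <- .config_schema[[k]]
    v <- if (k %in% names(user)) user[[k]] else spec$default
    if (is.logical(spec$default)) {
      if (!is.logical(v) || length(v) != 1L || is.na(v))
        stop(sprintf("config key '%s' must be TRUE/FALSE", k))
      return(v)
    }
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("config key '%s' must be a single number", k))
    if (v < spec$lo || v > spec$hi)
      stop(sprintf("config key '%s' = %s is outside [%s, %s]",
                   k, format(v), format(spec$lo), format(spec$hi)))
    if (isTRUE(spec$int)) v <- as.integer(v)
    v
  })
  names(cfg) <- names(.config_schema)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run provenance record
#'
#' Every pipeline run can log the effective configuration (defaults
#' included), the seed, and MD5 digests of its input files, so a result can
#' be traced back to exactly what produced it.
#'
#' @param config a `run_config` (see [load_run_config()]).
#' @param inputs character vector of input file paths (digested if they
#'   exist).
#' @param path output path for the YAML provenance record.
#' @param seed seed used for the run; defaults to `config$seed`.
#' @export
write_provenance <- function(config, inputs = character(), path,
                             seed = config$seed) {
  digests <- if (length(inputs)) {
    ex <- file.exists(inputs)
    d <- rep(NA_character_, length(inputs))
    d[ex] <- unname(tools::md5sum(inputs[ex]))
    setNames(as.list(d), inputs)
  } else list()
  rec <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed,
              config = unclass(config),
              input_md5 = digests)
  yaml::write_yaml(rec, path)
  invisible(path)
}
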