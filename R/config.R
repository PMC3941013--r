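## Run configuration: one key-value document holding the channel defaults,
## window sizes, voltage list and seeds, so a whole analysis is
## reproducible from config + inputs + seed.

#' Default run configuration
#'
#' @return Named list of all recognized configuration keys with their
#'   defaults: channel parameters (`T` 300 K, `conc` 0.15 M, `D`
#'   1.957e-9 m^2/s, `L` 17.2 nm, `q` +1, `epsr` 78.4), the
#'   force-averaging `window` (0.04 ns), the running-average
#'   `smooth_window` (2e-4 ns), the applied `voltages` (mV), the
#'   eccentricity `aggregate` mode, and the `seed`.
#' @export
default_config <- function() {
  list(T = 300, conc = 0.15, D = 1.957e-9, L = 17.2, q = 1, epsr = 78.4,
       window = 0.04, smooth_window = 2e-4,
       voltages = c(-(5:1), 1:5) * 5,
       aggregate = "per_frame", seed = 1L)
}

#' Load and validate a run configuration
#'
#' Starts from [default_config()], overlays an optional YAML file, then
#' explicit overrides. Unknown keys are rejected.
#'
#' @param path optional YAML file path.
#' @param overrides named list of explicit overrides.
#' @return The fully resolved configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  apply_keys <- function(cfg, kv, origin) {
    unknown <- setdiff(names(kv), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(kv)] <- kv
    cfg
  }
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    cfg <- apply_keys(cfg, yaml::read_yaml(path), path)
  }
  cfg <- apply_keys(cfg, overrides, "overrides")
  cfg
}

#' Channel parameters from a configuration
#'
#' @param cfg a configuration list from [load_config()].
#' @return A [channel_params()].
#' @export
config_channel_params <- function(cfg) {
  channel_params(T = cfg$T, c = cfg$conc, D = cfg$D, L = cfg$L, q = cfg$q,
                 epsr = cfg$epsr)
}

#' One structured log line per pipeline stage
#'
#' @param stage stage name.
#' @param ... named parameters to record.
#' @return The message string, invisibly; emitted via `message()`.
#' @export
log_stage <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), vapply(kv, function(x)
                  paste(format(x, digits = 6), collapse = ","), ""),
                  sep = "=", collapse = " "))
  message(msg)
  invisible(msg)
}
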