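# Run configuration: plain-text (YAML) configs, time normalization, and the
# orchestration entry point tying simulation and analysis into one
# reproducible run. A run is reproducible from its config alone.

#' Calibrated default DNA template levels
#'
#' Non-dimensional polymerase DNA levels producing the three qualitative
#' regimes under the calibrated default parameters and the canonical 4 h /
#' 16 h protocol: `low` (reporter washes out during self-regeneration),
#' `medium` (reporter exceeds the positive control), `high` (suppressed
#' reporter with a transient washout peak).
#'
#' @return Named numeric vector `c(low, medium, high)`.
#' @export
default_dna_levels <- function() c(low = 0.005, medium = 0.1, high = 2)

#' Parse a time to minutes
#'
#' Config times are minutes internally; a `"h"`/`"hours"` suffix (or
#' `"min"`) is accepted and normalized on load.
#'
#' @param x numeric (minutes) or a string like `"4h"`, `"90min"`.
#' @return Time in minutes.
#' @examples
#' parse_time_min("4h")    # 240
#' parse_time_min(90)      # 90
#' @export
parse_time_min <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*(h|hr|hours?|min|minutes?)?$", s))[[1]]
    if (length(m) < 2L || !nzchar(m[2]))
      stop(sprintf("cannot parse time '%s'", s), call. = FALSE)
    v <- as.numeric(m[2])
    unit <- if (length(m) >= 3L && nzchar(m[3])) m[3] else "min"
    if (startsWith(unit, "h")) v * 60 else v
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default run configuration
#'
#' The full, serializable configuration of a canonical titration run:
#' calibrated model parameters, the 20%/15-min dilution schedule with the
#' [0.20, 0.12, 0.04] segment geometry, the 4 h / 16 h three-phase protocol,
#' the low/medium/high template grid, analysis options and the noise model.
#'
#' @param seed integer seed recorded in the config.
#' @return Nested named list (schema version 1).
#' @seealso [load_run_config()], [run_from_config()]
#' @export
default_run_config <- function(seed = 1L) {
  p <- txtl_params()
  list(
    schema_version = 1L,
    kernel = "resource_dependent",
    seed = as.integer(seed),
    params = list(alpha = p$alpha, beta = p$beta, K = p$K,
                  E_total = p$E_total, K_M = p$K_M,
                  delta_m = p$delta_m, delta_p = p$delta_p),
    schedule = list(replaced_fraction = 0.2, cycle_interval = 15),
    segments = c(0.20, 0.12, 0.04),
    protocol = list(t_switch = c(240, 960), t_end = 1200),
    feeds = list(d_G = 1, p_T = 1, R = 1),
    titration = as.list(default_dna_levels()),
    analysis = list(sr_pc_time = 900, threshold_fraction = 0.1,
                    washout_margin = 0.05),
    noise = list(relative_sd = 0.02, background_offset = 0,
                 background_drift = 0)
  )
}

normalize_config <- function(cfg) {
  if (is.null(cfg$schema_version)) stop("config lacks schema_version", call. = FALSE)
  maybe <- function(x, f) if (is.null(x)) x else f(x)
  cfg$protocol$t_switch <- maybe(cfg$protocol$t_switch, parse_time_min)
  cfg$protocol$t_end <- maybe(cfg$protocol$t_end, parse_time_min)
  cfg$analysis$sr_pc_time <- maybe(cfg$analysis$sr_pc_time, parse_time_min)
  cfg$schedule$cycle_interval <- maybe(cfg$schedule$cycle_interval, parse_time_min)
  cfg$segments <- maybe(cfg$segments, as.numeric)
  if (!is.null(cfg$titration)) cfg$titration <- lapply(cfg$titration, as.numeric)
  cfg
}

validate_config <- function(cfg) {
  need <- c("schema_version", "kernel", "params", "schedule", "protocol",
            "feeds", "titration")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!length(unlist(cfg$titration)))
    stop("config field 'titration' must list at least one DNA level", call. = FALSE)
  config_params(cfg)     # side effect: validates parameter values
  config_schedule(cfg)
  invisible(cfg)
}

#' Load / save a run configuration
#'
#' Configurations are structured plain text (YAML). Times may carry an
#' `"h"` suffix in files and are normalized to minutes on load, so a
#' load-save-load round trip is lossless.
#'
#' @param path file path.
#' @param cfg a configuration list.
#' @return `load_run_config` returns the normalized, validated config;
#'   `save_run_config` returns `path` invisibly.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- normalize_config(cfg)
  validate_config(cfg)
  cfg
}

#' @rdname load_run_config
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname config_objects
#' @export
config_params <- function(cfg) do.call(txtl_params, cfg$params)

#' Build package objects from a configuration
#'
#' Helpers turning the serializable config into the objects the simulation
#' and analysis layers consume.
#'
#' @param cfg a configuration list (see [default_run_config()]).
#' @return [config_params()]: a [txtl_params()]; [config_schedule()]: a
#'   [dilution_schedule()]; [config_noise()]: a [noise_model()].
#' @name config_objects
#' @export
config_schedule <- function(cfg)
  dilution_schedule(cfg$schedule$replaced_fraction, cfg$schedule$cycle_interval)

#' @rdname config_objects
#' @export
config_noise <- function(cfg)
  noise_model(relative_sd = cfg$noise$relative_sd %||% 0,
              background_offset = cfg$noise$background_offset %||% 0,
              background_drift = cfg$noise$background_drift %||% 0,
              seed = cfg$seed %||% 1L)

#' Run a full titration experiment from a configuration
#'
#' The orchestration entry point: simulates the positive control, negative
#' control and one self-regeneration experiment per titration level, and
#' computes the metric table. When `outdir` is given, every trace is written
#' as CSV (with its metadata sidecar) together with `metrics.csv` and the
#' resolved config, so the run is reproducible from the output directory
#' alone.
#'
#' @param cfg a configuration list or a path to a YAML config.
#' @param outdir optional output directory.
#' @return List with `bundle` (the normalized [experiment_bundle()]) and
#'   `metrics` (data frame, one row per self-regeneration experiment).
#' @export
run_from_config <- function(cfg, outdir = NULL) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  cfg <- normalize_config(cfg)
  validate_config(cfg)
  bundle <- simulate_experiment(
    params = config_params(cfg),
    d_T = unlist(cfg$titration),
    kernel = cfg$kernel,
    noise = config_noise(cfg),
    t_end = cfg$protocol$t_end,
    t_switch = cfg$protocol$t_switch,
    d_G = cfg$feeds$d_G, p_T_feed = cfg$feeds$p_T, R_feed = cfg$feeds$R,
    schedule = config_schedule(cfg),
    segments = cfg$segments %||% c(0.20, 0.12, 0.04))
  bundle <- normalize_to_pc(bundle)
  metrics <- compute_metrics(bundle, config_schedule(cfg),
                             at_time = cfg$analysis$sr_pc_time,
                             threshold_fraction = cfg$analysis$threshold_fraction,
                             margin = cfg$analysis$washout_margin)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_trace(bundle$pc, file.path(outdir, "positive_control.csv"))
    write_trace(bundle$nc, file.path(outdir, "negative_control.csv"))
    for (nm in names(bundle$sr))
      write_trace(bundle$sr[[nm]],
                  file.path(outdir, paste0("sr_", gsub("[^A-Za-z0-9._-]", "_", nm), ".csv")))
    utils::write.csv(metrics, file.path(outdir, "metrics.csv"), row.names = FALSE)
    save_run_config(cfg, file.path(outdir, "config.yaml"))
  }
  list(bundle = bundle, metrics = metrics, config = cfg)
}
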