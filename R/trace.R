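# Trace container and plain-text I/O.
#
# A trace is a data frame sampled on the uniform cycle grid: column 1 is
# time_min, then one column per observable, and a final phase column.
# Metadata (schedule, parameters, kernel) travels in attributes in memory and
# in a YAML sidecar on disk.

new_trace <- function(df, schedule, params = NULL, kernel = NULL, meta = list()) {
  stopifnot(is.data.frame(df), "time_min" %in% names(df))
  if (is.unsorted(df$time_min, strictly = TRUE))
    stop("trace times must be strictly increasing", call. = FALSE)
  structure(df, class = c("txtl_trace", "data.frame"),
            schedule = schedule, params = params, kernel = kernel, meta = meta)
}

#' @export
print.txtl_trace <- function(x, ...) {
  cat(sprintf("TX-TL chemostat trace: %d samples, %g-%g min, kernel: %s\n",
              nrow(x), min(x$time_min), max(x$time_min),
              attr(x, "kernel") %||% "?"))
  cat("  species order:", paste(setdiff(names(x), c("time_min", "phase")),
                                collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trace_channels <- function(trace) setdiff(names(trace), c("time_min", "phase"))

#' Extract the value of a trace channel at a time point
#'
#' @param trace a trace data frame.
#' @param at_time time in minutes; must lie on the sampling grid.
#' @param channel column name (default the reporter protein).
#' @return Numeric scalar.
#' @export
trace_value_at <- function(trace, at_time, channel = "p_G") {
  i <- which(abs(trace$time_min - at_time) < 1e-6)
  if (length(i) != 1L)
    stop(sprintf("time %g min is not on the trace grid", at_time), call. = FALSE)
  trace[[channel]][i]
}

check_uniform_grid <- function(trace, cycle_interval, tol = 1e-6) {
  dt <- diff(trace$time_min)
  if (any(abs(dt - cycle_interval) > tol))
    stop("trace is not uniformly sampled at the cycle interval", call. = FALSE)
  invisible(trace)
}

#' Write / read a trace as a delimited text table
#'
#' Traces are written as plain CSV (column 1 `time_min` in minutes, one
#' column per species in the canonical state order, final column `phase`)
#' with a YAML sidecar `<path>.meta.yaml` carrying the schedule, parameters,
#' kernel name and a units note. `read_trace` restores both.
#'
#' @param trace a trace as returned by [run_chemostat()].
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   trace.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  sched <- attr(trace, "schedule")
  par <- attr(trace, "params")
  meta <- list(
    format = "txtl_trace/1",
    units = "time_min in minutes; concentrations non-dimensional",
    state_order = trace_channels(trace),
    kernel = attr(trace, "kernel"),
    schedule = if (!is.null(sched)) unclass(sched),
    params = if (!is.null(par)) unclass(par))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.yaml")
  schedule <- NULL; params <- NULL; kernel <- NULL
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$schedule))
      schedule <- dilution_schedule(meta$schedule$replaced_fraction,
                                    meta$schedule$cycle_interval)
    if (!is.null(meta$params)) params <- do.call(txtl_params, meta$params)
    kernel <- meta$kernel
  }
  new_trace(df, schedule = schedule, params = params, kernel = kernel)
}
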