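# Figures of merit computed from traces: normalization, synthesis rates,
# SR/PC ratio, regeneration duration, robustness, yield, theoretical maximal
# yield, washout-peak detection and Pareto fronts.

#' Experiment bundle
#'
#' Groups the traces of one experiment set on a shared time grid: an optional
#' positive control (full PURE, reporter only), an optional negative control
#' (delta-PURE, no template for the regenerated protein), and one or more
#' self-regeneration traces with their DNA-input annotations.
#'
#' @param sr named list of self-regeneration traces.
#' @param pc,nc positive / negative control traces (or NULL).
#' @param dna_inputs list (parallel to `sr`) of named numeric vectors of DNA
#'   template inputs per gene (reporter included), used for bookkeeping and
#'   [theoretical_max_yield()].
#' @return Object of class `experiment_bundle`.
#' @export
experiment_bundle <- function(sr, pc = NULL, nc = NULL, dna_inputs = NULL) {
  if (inherits(sr, "txtl_trace")) sr <- list(sr)
  if (!length(sr)) stop("at least one self-regeneration trace required", call. = FALSE)
  if (is.null(names(sr)) || any(!nzchar(names(sr))))
    names(sr) <- paste0("sr_", seq_along(sr))
  ref <- sr[[1]]$time_min
  for (tr in c(sr, Filter(Negate(is.null), list(pc, nc)))) {
    if (length(tr$time_min) != length(ref) || any(abs(tr$time_min - ref) > 1e-6))
      stop("all traces in a bundle must share one time grid", call. = FALSE)
  }
  structure(list(pc = pc, nc = nc, sr = sr,
                 dna_inputs = dna_inputs, normalization = NULL),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("Experiment bundle: %s%s%d self-regeneration trace(s)\n",
              if (!is.null(x$pc)) "positive control, " else "",
              if (!is.null(x$nc)) "negative control, " else "",
              length(x$sr)))
  if (!is.null(x$normalization))
    cat(sprintf("  normalized (reference max = %g)\n", x$normalization))
  invisible(x)
}

bundle_traces <- function(bundle) {
  c(Filter(Negate(is.null), list(pc = bundle$pc, nc = bundle$nc)), bundle$sr)
}

#' Normalize a bundle to the positive-control maximum
#'
#' Divides the reporter channel of every trace by the maximum of the
#' positive-control series; when no positive control is present, the overall
#' maximum across all traces is used instead. The normalization constant is
#' recorded in `bundle$normalization`.
#'
#' @param bundle an [experiment_bundle()].
#' @param channel reporter channel name (default `"p_G"`).
#' @return The bundle with the channel rescaled.
#' @export
normalize_to_pc <- function(bundle, channel = "p_G") {
  stopifnot(inherits(bundle, "experiment_bundle"))
  ref <- if (!is.null(bundle$pc)) max(bundle$pc[[channel]])
         else max(vapply(bundle_traces(bundle), function(tr) max(tr[[channel]]),
                         numeric(1)))
  if (!is.finite(ref) || ref <= 0)
    stop("degenerate normalization: reference signal has no positive maximum",
         call. = FALSE)
  rescale <- function(tr) { if (!is.null(tr)) tr[[channel]] <- tr[[channel]] / ref; tr }
  bundle$pc <- rescale(bundle$pc)
  bundle$nc <- rescale(bundle$nc)
  bundle$sr <- lapply(bundle$sr, rescale)
  bundle$normalization <- ref
  bundle
}

#' Per-sample synthesis rate net of dilution
#'
#' Infers production between consecutive samples, removing the known
#' dilution: `rate(t_n) = [c(t_{n+1}) - (1 - F) c(t_n)] / dt` where `F` is
#' the replaced fraction per cycle. A species at steady state therefore has
#' rate `F c / dt` (synthesis balancing dilution) and a purely diluting
#' species has rate 0.
#'
#' @param trace a trace sampled uniformly at the cycle interval.
#' @param schedule the [dilution_schedule()] in force (default: the trace's
#'   own schedule attribute).
#' @param channel channel name.
#' @return Numeric vector, one rate per sample (concentration per minute);
#'   the last entry is `NA` (no following sample).
#' @export
synthesis_rate <- function(trace, schedule = NULL, channel = "p_G") {
  schedule <- schedule %||% attr(trace, "schedule")
  if (is.null(schedule)) stop("a dilution schedule is required", call. = FALSE)
  check_uniform_grid(trace, schedule$cycle_interval)
  c0 <- trace[[channel]]
  n <- length(c0)
  F_tot <- schedule$replaced_fraction
  rate <- c((c0[-1L] - (1 - F_tot) * c0[-n]) / schedule$cycle_interval, NA_real_)
  rate
}

#' Ratio of self-regeneration to positive-control signal
#'
#' Reporter level of each self-regeneration trace divided by the positive
#' control at a given time (default 15 h = 900 min, the comparison point of
#' the template titration).
#'
#' @param bundle an [experiment_bundle()] with a positive control.
#' @param at_time time in minutes, on the sampling grid.
#' @param channel channel name.
#' @return Named numeric vector, one ratio per self-regeneration trace.
#' @export
sr_pc_ratio <- function(bundle, at_time = 900, channel = "p_G") {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (is.null(bundle$pc)) stop("bundle has no positive control", call. = FALSE)
  ref <- trace_value_at(bundle$pc, at_time, channel)
  if (ref == 0) stop("degenerate ratio: positive control is 0 at at_time", call. = FALSE)
  vapply(bundle$sr, function(tr) trace_value_at(tr, at_time, channel) / ref,
         numeric(1))
}

sr_phase_start <- function(trace, sr_start = NULL) {
  if (!is.null(sr_start)) return(sr_start)
  i <- which(trace$phase == "self-regeneration")
  if (!length(i)) stop("trace has no self-regeneration phase", call. = FALSE)
  trace$time_min[i[1L]]
}

#' Duration of sustained self-regeneration
#'
#' Operationalizes "time the system self-regenerates beyond the negative
#' control": the last time at which the self-regeneration synthesis rate
#' exceeds both the negative-control synthesis rate and a fraction
#' (`threshold_fraction`, default 10%) of the trace's own steady-phase rate,
#' measured from the start of the self-regeneration phase. The steady-phase
#' reference is the median synthesis rate over the first `steady_window`
#' minutes of that phase. Never negative.
#'
#' @param sr_trace,nc_trace self-regeneration and negative-control traces on
#'   a common grid.
#' @param schedule the [dilution_schedule()] (default: trace attribute).
#' @param threshold_fraction fraction of the steady-phase rate, in (0, 1).
#' @param channel channel name.
#' @param sr_start start of the self-regeneration phase in minutes
#'   (default: from the trace's phase labels).
#' @param steady_window minutes over which the steady-phase rate is taken.
#' @return Duration in hours.
#' @export
regeneration_duration <- function(sr_trace, nc_trace, schedule = NULL,
                                  threshold_fraction = 0.1, channel = "p_G",
                                  sr_start = NULL, steady_window = 240) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  if (length(sr_trace$time_min) != length(nc_trace$time_min) ||
      any(abs(sr_trace$time_min - nc_trace$time_min) > 1e-6))
    stop("traces must share a common time grid", call. = FALSE)
  schedule <- schedule %||% attr(sr_trace, "schedule")
  sr_start <- sr_phase_start(sr_trace, sr_start)
  if (max(sr_trace$time_min) <= sr_start)
    stop("trace does not extend into the self-regeneration phase", call. = FALSE)
  r_sr <- synthesis_rate(sr_trace, schedule, channel)
  r_nc <- synthesis_rate(nc_trace, schedule, channel)
  t <- sr_trace$time_min
  in_ref <- t >= sr_start & t < sr_start + steady_window & !is.na(r_sr)
  steady <- stats::median(r_sr[in_ref])
  ok <- !is.na(r_sr) & t >= sr_start & r_sr > r_nc & r_sr > threshold_fraction * steady
  if (!any(ok)) return(0)
  max(0, (max(t[ok]) - sr_start) / 60)
}

#' Robustness score
#'
#' Self-regeneration duration normalized by 24 h and capped at 1: a system
#' sustaining regeneration for 24 h or longer scores exactly 1; shorter
#' durations score linearly between 0 and 1.
#'
#' @param duration_hours duration in hours, >= 0.
#' @return Score in `[0, 1]`.
#' @examples
#' robustness(26)  # 1
#' robustness(12)  # 0.5
#' @export
robustness <- function(duration_hours) {
  if (any(duration_hours < 0)) stop("duration must be >= 0", call. = FALSE)
  pmin(duration_hours / 24, 1)
}

#' Yield of non-essential protein during self-regeneration
#'
#' Mean normalized reporter level over a window of the self-regeneration
#' phase (default: its last 4 h). A system that never expressed the missing
#' essential protein yields ~0.
#'
#' @param trace a (normalized) trace.
#' @param window numeric length 2, window in minutes; default: last 4 h of
#'   the self-regeneration phase taken from the phase labels.
#' @param channel channel name.
#' @return Dimensionless yield >= 0.
#' @export
yield_metric <- function(trace, window = NULL, channel = "p_G") {
  if (is.null(window)) {
    i <- which(trace$phase == "self-regeneration")
    if (!length(i)) stop("trace has no self-regeneration phase", call. = FALSE)
    end <- trace$time_min[i[length(i)]]
    window <- c(end - 240, end)
  }
  sel <- trace$time_min >= window[1] & trace$time_min <= window[2]
  if (!any(sel)) stop("empty yield window", call. = FALSE)
  mean(trace[[channel]][sel])
}

#' Theoretical maximal yield under proportional allocation
#'
#' Upper bound on normalized reporter yield when additional genes load the
#' system: the positive-control level scaled by the reporter's share of
#' total DNA input, assuming equal synthesis rate per template (the
#' proportional-allocation reading; the assumption is recorded in the
#' result's `"assumption"` attribute).
#'
#' @param pc_level positive-control reporter level (normalized, usually 1).
#' @param dna_inputs named numeric vector of DNA inputs including the
#'   reporter (any concentration unit, used as ratios).
#' @param reporter name of the reporter entry in `dna_inputs`.
#' @return Dimensionless level with attribute `"assumption"`.
#' @examples
#' theoretical_max_yield(1, c(eGFP = 2, AsnRS = 0.5, LeuRS = 0.5,
#'                            ArgRS = 0.5, TyrRS = 0.5))
#' @export
theoretical_max_yield <- function(pc_level, dna_inputs, reporter = "eGFP") {
  if (!reporter %in% names(dna_inputs))
    stop("dna_inputs must include the reporter gene", call. = FALSE)
  total <- sum(dna_inputs)
  if (total <= 0) stop("total DNA input must be > 0", call. = FALSE)
  structure(pc_level * dna_inputs[[reporter]] / total,
            assumption = "equal synthesis rate per DNA template; capacity split by DNA fraction")
}

#' Detect a transient peak during the washout phase
#'
#' A washout peak is present when the reporter maximum over the washout
#' phase exceeds the level at washout start by a margin (default 5%) and is
#' later followed by a decline below that starting level — the signature of
#' resource load being released before the regenerated protein dilutes below
#' critical levels.
#'
#' @param trace a trace extending at least 2 h past `washout_start`.
#' @param washout_start start of the washout phase in minutes (default: from
#'   the phase labels).
#' @param margin required fractional excess over the starting level.
#' @param channel channel name.
#' @return List with `present` (logical), `time` (minutes) and `height`
#'   (peak level); `time`/`height` are `NA` when absent.
#' @export
detect_washout_peak <- function(trace, washout_start = NULL, margin = 0.05,
                                channel = "p_G") {
  if (is.null(washout_start)) {
    i <- which(trace$phase == "washout")
    if (!length(i)) stop("trace has no washout phase", call. = FALSE)
    washout_start <- trace$time_min[i[1L]]
  }
  if (max(trace$time_min) < washout_start + 120)
    stop("trace must extend at least 2 h past washout start", call. = FALSE)
  sel <- trace$time_min >= washout_start
  y <- trace[[channel]][sel]
  t <- trace$time_min[sel]
  lvl0 <- y[1L]
  i_max <- which.max(y)
  exceeds <- y[i_max] > lvl0 * (1 + margin)
  declines <- i_max < length(y) && any(y[(i_max + 1L):length(y)] < lvl0)
  if (exceeds && declines) {
    list(present = TRUE, time = t[i_max], height = y[i_max])
  } else {
    list(present = FALSE, time = NA_real_, height = NA_real_)
  }
}

#' Pareto front of yield-robustness points
#'
#' Returns the subset of experiments not dominated in both yield and
#' robustness (maximization). A point is dominated if another point is at
#' least as good in both coordinates and strictly better in one; exact ties
#' are all retained, and input order is preserved.
#'
#' @param metric_sets a data frame with columns `yield` and `robustness`
#'   (e.g. from [compute_metrics()]), or a 2-column matrix.
#' @return The non-dominated rows, in input order.
#' @examples
#' pts <- data.frame(yield = c(0.9, 0.5, 0.95), robustness = c(1, 1, 0.2))
#' pareto_front(pts)
#' @export
pareto_front <- function(metric_sets) {
  ms <- as.data.frame(metric_sets)
  if (!all(c("yield", "robustness") %in% names(ms))) {
    stopifnot(ncol(ms) >= 2L)
    names(ms)[1:2] <- c("yield", "robustness")
  }
  n <- nrow(ms)
  if (n < 1L) stop("at least one point required", call. = FALSE)
  y <- ms$yield; r <- ms$robustness
  ge_y <- outer(y, y, `>=`); ge_r <- outer(r, r, `>=`)
  strict <- outer(y, y, `>`) | outer(r, r, `>`)
  dominated <- vapply(seq_len(n), function(i)
    any(ge_y[, i] & ge_r[, i] & strict[, i]), logical(1))
  ms[!dominated, , drop = FALSE]
}

#' Metric set for every self-regeneration experiment in a bundle
#'
#' Normalizes the bundle to its positive control and computes, per
#' self-regeneration trace: yield, regeneration duration, robustness, the
#' SR/PC ratio at `at_time`, and the washout-peak descriptor (when the
#' protocol has a washout phase).
#'
#' @param bundle an [experiment_bundle()] with positive and negative
#'   controls.
#' @param schedule the [dilution_schedule()] (default: trace attribute).
#' @param at_time SR/PC comparison time, minutes.
#' @param threshold_fraction see [regeneration_duration()].
#' @param margin see [detect_washout_peak()].
#' @param channel channel name.
#' @return Data frame, one row per self-regeneration experiment.
#' @export
compute_metrics <- function(bundle, schedule = NULL, at_time = 900,
                            threshold_fraction = 0.1, margin = 0.05,
                            channel = "p_G") {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (is.null(bundle$normalization)) bundle <- normalize_to_pc(bundle, channel)
  schedule <- schedule %||% attr(bundle$sr[[1]], "schedule")
  tr1 <- bundle$sr[[1]]
  has_wash <- "washout" %in% tr1$phase &&
    max(tr1$time_min) >= tr1$time_min[match("washout", tr1$phase)] + 120
  ratios <- if (!is.null(bundle$pc)) sr_pc_ratio(bundle, at_time, channel)
            else rep(NA_real_, length(bundle$sr))
  rows <- lapply(seq_along(bundle$sr), function(i) {
    tr <- bundle$sr[[i]]
    dur <- if (!is.null(bundle$nc))
      regeneration_duration(tr, bundle$nc, schedule, threshold_fraction,
                            channel = channel) else NA_real_
    pk <- if (has_wash) detect_washout_peak(tr, margin = margin, channel = channel)
          else list(present = NA, time = NA_real_, height = NA_real_)
    data.frame(experiment = names(bundle$sr)[i],
               yield = yield_metric(tr, channel = channel),
               regeneration_duration_h = dur,
               robustness = if (is.na(dur)) NA_real_ else robustness(dur),
               sr_pc_ratio = unname(ratios[i]),
               washout_peak = pk$present,
               washout_peak_time_min = pk$time,
               washout_peak_height = pk$height,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(bundle$dna_inputs)) {
    out$dna_inputs <- vapply(seq_len(nrow(out)), function(i) {
      di <- bundle$dna_inputs[[i]]
      paste(sprintf("%s=%g", names(di), di), collapse = ";")
    }, character(1))
  }
  rownames(out) <- NULL
  out
}
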