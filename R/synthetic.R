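# Synthetic fluorescence time-series generation: mechanistic experiment
# bundles with a phenomenological tracer channel and measurement noise, exact
# parametric trace shapes for analysis unit tests, and least-squares recovery
# of the model parameters from synthetic bundles.

#' Measurement noise model
#'
#' Multiplicative Gaussian noise plus an additive background with linear
#' drift, truncated at zero (fluorescence is nonnegative). Identical seeds
#' reproduce identical traces bit-for-bit (R's default Mersenne-Twister
#' generator).
#'
#' @param relative_sd multiplicative noise fraction (>= 0; default 0.02).
#' @param background_offset additive background, fluorescence units.
#' @param background_drift background drift, units per hour.
#' @param seed integer RNG seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(relative_sd = 0.02, background_offset = 0,
                        background_drift = 0, seed = 1L) {
  if (relative_sd < 0) stop("relative_sd must be >= 0", call. = FALSE)
  structure(list(relative_sd = relative_sd,
                 background_offset = background_offset,
                 background_drift = background_drift,
                 seed = as.integer(seed)),
            class = "noise_model")
}

with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

apply_noise <- function(values, time_min, noise) {
  if (noise$relative_sd > 0)
    values <- values * (1 + stats::rnorm(length(values), 0, noise$relative_sd))
  values <- values + noise$background_offset + noise$background_drift * time_min / 60
  pmax(values, 0)
}

tracer_series <- function(protocol, schedule, t_end, full_pure_level = 1) {
  dt <- schedule$cycle_interval
  F_tot <- schedule$replaced_fraction
  times <- seq(0, t_end, by = dt)
  fed <- vapply(times, function(t) {
    lv <- unlist(lapply(phase_at(protocol, t)$feeds, function(f)
      f$species_levels["tracer"]))
    if (length(lv) && any(!is.na(lv))) sum(lv, na.rm = TRUE) else 0
  }, numeric(1))
  x <- numeric(length(times))
  x[1L] <- fed[1L] * full_pure_level
  for (i in seq_along(times)[-1L])
    x[i] <- (1 - F_tot) * x[i - 1L] + F_tot * fed[i - 1L] * full_pure_level
  x
}

#' Simulate a full experiment bundle with measurement noise
#'
#' Runs the chemostat for the positive control, the negative control and a
#' self-regeneration experiment per polymerase DNA level, appends an
#' mScarlet-like tracer channel that follows full-PURE feed presence under
#' pure dilution kinetics, and applies the measurement-noise model to the
#' fluorescence channels (`p_G` and `tracer`). With zero noise and zero
#' background the bundle equals the raw simulation exactly.
#'
#' @param params a [txtl_params()] object.
#' @param d_T numeric vector of polymerase DNA template levels (one
#'   self-regeneration trace each); names are used as experiment labels.
#' @param kernel reaction kernel, as in [run_chemostat()].
#' @param noise a [noise_model()].
#' @param t_end experiment length in minutes.
#' @param t_switch phase-switch times in minutes.
#' @param d_G,p_T_feed,R_feed feed levels, see [canonical_protocol()].
#' @param segments ordered segment fractions, see [canonical_feeds()].
#' @param schedule a [dilution_schedule()].
#' @param rtol,atol solver tolerances.
#' @return An [experiment_bundle()]; the generating configuration is stored
#'   in `attr(, "config")` (used by [recover_parameters()]).
#' @export
simulate_experiment <- function(params = txtl_params(),
                                d_T = default_dna_levels()[["medium"]],
                                kernel = "resource_dependent",
                                noise = noise_model(),
                                t_end = 1200, t_switch = c(240, 960),
                                d_G = 1, p_T_feed = 1, R_feed = 1,
                                schedule = dilution_schedule(),
                                segments = c(0.20, 0.12, 0.04),
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(noise, "noise_model"))
  proto_for <- function(role, dT = 0)
    canonical_protocol(role, d_T = dT, d_G = d_G, p_T_feed = p_T_feed,
                       R_feed = R_feed, t_switch = t_switch, t_end = t_end,
                       schedule = schedule, segments = segments)
  run_one <- function(role, dT = 0) {
    proto <- proto_for(role, dT)
    tr <- run_chemostat(params, proto, schedule, t_end = t_end,
                        kernel = kernel, rtol = rtol, atol = atol)
    tr$tracer <- tracer_series(proto, schedule, t_end)
    tr
  }
  if (is.null(names(d_T))) names(d_T) <- paste0("d_T=", signif(d_T, 3))
  pc <- run_one("pc")
  nc <- run_one("nc")
  sr <- lapply(d_T, function(dT) run_one("sr", dT))
  with_local_seed(noise$seed, {
    noisify <- function(tr) {
      for (ch in c("p_G", "tracer"))
        tr[[ch]] <- apply_noise(tr[[ch]], tr$time_min, noise)
      tr
    }
    pc <- noisify(pc); nc <- noisify(nc); sr <- lapply(sr, noisify)
  })
  bundle <- experiment_bundle(sr, pc = pc, nc = nc,
                              dna_inputs = lapply(d_T, function(dT)
                                c(eGFP = d_G, T7 = unname(dT))))
  attr(bundle, "config") <- list(kernel = kernel, d_T = d_T, t_end = t_end,
                                 t_switch = t_switch, d_G = d_G,
                                 p_T_feed = p_T_feed, R_feed = R_feed,
                                 schedule = schedule, segments = segments,
                                 noise = noise, params = params)
  bundle
}

#' Exact parametric trace shapes
#'
#' Piecewise-constructed reporter traces on the cycle grid, used as ground
#' truth for analysis unit tests: each segment either holds the current
#' level, ramps linearly to a target, or decays under pure dilution
#' (multiplying by `1 - replaced_fraction` per cycle). Breakpoint times are
#' recoverable by the analysis operations to within one sample.
#'
#' @param segments list of segments, each `list(until = <minutes>,
#'   mode = "hold" | "linear" | "dilute", target = <level>)` (`target` only
#'   for `"linear"`). Segment ends must be increasing and on the grid.
#' @param initial starting level at t = 0.
#' @param schedule a [dilution_schedule()].
#' @param t_switch phase-switch times used for the phase labels.
#' @return A trace with columns `time_min`, `p_G`, `phase`.
#' @examples
#' parametric_trace(list(list(until = 600, mode = "hold"),
#'                       list(until = 1200, mode = "dilute")), initial = 1)
#' @export
parametric_trace <- function(segments, initial = 0,
                             schedule = dilution_schedule(),
                             t_switch = c(240, 960)) {
  dt <- schedule$cycle_interval
  ends <- vapply(segments, function(s) s$until, numeric(1))
  if (is.unsorted(ends, strictly = TRUE) || any(ends <= 0))
    stop("segment end times must be positive and strictly increasing", call. = FALSE)
  if (any(abs(ends / dt - round(ends / dt)) > 1e-9))
    stop("segment breakpoints must lie on the sampling grid", call. = FALSE)
  t_end <- ends[length(ends)]
  times <- seq(0, t_end, by = dt)
  y <- numeric(length(times))
  y[1L] <- initial
  seg_start <- c(0, ends[-length(ends)])
  for (i in seq_along(times)[-1L]) {
    t <- times[i]
    k <- which(t > seg_start & t <= ends)[1L]
    seg <- segments[[k]]
    y[i] <- switch(match.arg(seg$mode, c("hold", "linear", "dilute")),
      hold = y[i - 1L],
      linear = {
        start_level <- y[max(which(times <= seg_start[k]))]
        start_level + (seg$target - start_level) * (t - seg_start[k]) /
          (ends[k] - seg_start[k])
      },
      dilute = (1 - schedule$replaced_fraction) * y[i - 1L])
  }
  phases <- cut(times, breaks = c(-Inf, t_switch, Inf),
                labels = c("kick-start", "self-regeneration", "washout"),
                right = FALSE)
  # samples exactly at a switch belong to the new phase; the last usable
  # label is clamped to the phases the trace actually reaches
  new_trace(data.frame(time_min = times, p_G = y, phase = as.character(phases),
                       stringsAsFactors = FALSE),
            schedule = schedule, kernel = "parametric")
}

#' Recover model parameters from a synthetic bundle
#'
#' Least-squares fit of the resource-dependent parameters (alpha, beta, K)
#' to the reporter channels of a template titration bundle produced by
#' [simulate_experiment()]: the same protocols are re-simulated at candidate
#' parameters and residuals against the observed `p_G` series (all
#' self-regeneration traces plus the positive control) are minimized with
#' the Levenberg-Marquardt algorithm on log-parameters.
#'
#' @param bundle a bundle from [simulate_experiment()] (its generating
#'   configuration attribute is required).
#' @param initial_guess a [txtl_params()] object used as the starting point.
#' @param kernel kernel to fit (default: the bundle's own).
#' @param rtol solver relative tolerance used inside the fit (looser than
#'   the simulation default for speed; the optimum is insensitive to it).
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return List with `params` (fitted [txtl_params()]), `estimate` (named
#'   vector alpha/beta/K), `deviance`, `niter`, `converged` (logical;
#'   non-convergence is reported, not raised), `message`, and `start`.
#' @export
recover_parameters <- function(bundle, initial_guess, kernel = NULL,
                               rtol = 1e-6, maxiter = 40) {
  cfg <- attr(bundle, "config")
  if (is.null(cfg))
    stop("bundle carries no generating configuration; use simulate_experiment()",
         call. = FALSE)
  stopifnot(inherits(initial_guess, "txtl_params"))
  kernel <- kernel %||% cfg$kernel
  obs <- c(unlist(lapply(bundle$sr, function(tr) tr$p_G)),
           if (!is.null(bundle$pc)) bundle$pc$p_G)
  simulate_pg <- function(p) {
    run <- function(role, dT = 0)
      run_chemostat(p, canonical_protocol(role, d_T = dT, d_G = cfg$d_G,
                                          p_T_feed = cfg$p_T_feed,
                                          R_feed = cfg$R_feed,
                                          t_switch = cfg$t_switch,
                                          t_end = cfg$t_end,
                                          schedule = cfg$schedule,
                                          segments = cfg$segments),
                    cfg$schedule, t_end = cfg$t_end, kernel = kernel,
                    rtol = rtol, atol = rtol * 1e-2)$p_G
    c(unlist(lapply(cfg$d_T, function(dT) run("sr", dT))),
      if (!is.null(bundle$pc)) run("pc"))
  }
  resid_fn <- function(logp) {
    p <- txtl_params(alpha = exp(logp[1]), beta = exp(logp[2]), K = exp(logp[3]),
                     E_total = initial_guess$E_total, K_M = initial_guess$K_M)
    simulate_pg(p) - obs
  }
  start <- log(c(alpha = initial_guess$alpha, beta = initial_guess$beta,
                 K = initial_guess$K))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ptol = 1e-8, ftol = 1e-10))
  est <- exp(fit$par)
  names(est) <- c("alpha", "beta", "K")
  list(params = txtl_params(alpha = est[["alpha"]], beta = est[["beta"]],
                            K = est[["K"]], E_total = initial_guess$E_total,
                            K_M = initial_guess$K_M),
       estimate = est,
       deviance = fit$deviance,
       niter = fit$niter,
       converged = fit$info %in% 1:4,
       message = fit$message,
       start = exp(start))
}
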