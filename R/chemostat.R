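# Discrete-dilution chemostat engine: dilution mathematics, feed geometry,
# phase protocols and event-driven integration of a reaction kernel.

#' Dilution schedule
#'
#' A periodic replacement of a fixed reactor-volume fraction. The canonical
#' operation replaces 20% of the volume every 15 minutes.
#'
#' @param replaced_fraction volume fraction replaced per cycle, in (0, 1).
#' @param cycle_interval minutes between replacements, > 0.
#' @return Object of class `dilution_schedule`.
#' @examples
#' dilution_schedule()           # 20% every 15 min
#' @export
dilution_schedule <- function(replaced_fraction = 0.2, cycle_interval = 15) {
  if (!is.numeric(replaced_fraction) || length(replaced_fraction) != 1L ||
      replaced_fraction <= 0 || replaced_fraction >= 1)
    stop("replaced_fraction must be in (0, 1)", call. = FALSE)
  if (!is.numeric(cycle_interval) || length(cycle_interval) != 1L || cycle_interval <= 0)
    stop("cycle_interval must be > 0", call. = FALSE)
  structure(list(replaced_fraction = replaced_fraction,
                 cycle_interval = cycle_interval),
            class = "dilution_schedule")
}

#' @export
print.dilution_schedule <- function(x, ...) {
  mu <- dilution_rate(x$replaced_fraction, x$cycle_interval)
  cat(sprintf("Dilution schedule: %.0f%% replaced every %g min\n",
              100 * x$replaced_fraction, x$cycle_interval))
  cat(sprintf("  dilution rate mu = %.6f / min, residence time = %.1f min, dilution time t_d = %.1f min\n",
              mu, residence_time(mu), dilution_time(mu)))
  invisible(x)
}

#' Dilution rate of a discrete replacement schedule
#'
#' The effective continuous dilution rate `mu = -ln(1 - f) / t` of a schedule
#' replacing fraction `f` of the reactor volume every `t` minutes, from
#' `mu = -ln(C_t / C_0) / t` applied to one cycle of pure dilution.
#'
#' @param replaced_fraction volume fraction replaced per cycle, in (0, 1).
#' @param cycle_interval minutes between replacements, > 0.
#' @return Dilution rate in 1/min.
#' @examples
#' dilution_rate(0.2, 15)   # 0.014876 / min
#' @export
dilution_rate <- function(replaced_fraction, cycle_interval) {
  if (any(replaced_fraction <= 0) || any(replaced_fraction >= 1))
    stop("replaced_fraction must be in (0, 1)", call. = FALSE)
  if (any(cycle_interval <= 0)) stop("cycle_interval must be > 0", call. = FALSE)
  -log(1 - replaced_fraction) / cycle_interval
}

#' Dilution time (content half-life) and residence time
#'
#' `dilution_time` is the half-life of reactor contents under dilution,
#' `t_d = ln(2) / mu`; `residence_time` is the mean residence time `1 / mu`.
#'
#' @param rate dilution rate in 1/min, > 0.
#' @return Time in minutes.
#' @examples
#' mu <- dilution_rate(0.2, 15)
#' dilution_time(mu)    # ~46.6 min
#' residence_time(mu)   # ~67.2 min
#' @export
dilution_time <- function(rate) {
  if (any(rate <= 0)) stop("rate must be > 0", call. = FALSE)
  log(2) / rate
}

#' @rdname dilution_time
#' @export
residence_time <- function(rate) {
  if (any(rate <= 0)) stop("rate must be > 0", call. = FALSE)
  1 / rate
}

#' Fresh-volume contribution of sequentially loaded segments
#'
#' Feed solutions are loaded sequentially through nested reactor segments:
#' solution j fills fraction `s_j` of the reactor and is then partially
#' overwritten by the next (smaller) segment. Solution j therefore
#' contributes `s_j - s_{j+1}` of fresh volume, and the last contributes its
#' full segment. The canonical geometry [0.20, 0.12, 0.04] for
#' energy / protein+ribosome / DNA solutions yields [0.08, 0.08, 0.04].
#'
#' @param segment_fractions strictly decreasing fractions in (0, 1].
#' @return Fresh-volume fraction contributed per solution (sums to the first
#'   segment fraction).
#' @examples
#' segment_composition(c(0.20, 0.12, 0.04))  # 0.08 0.08 0.04
#' @export
segment_composition <- function(segment_fractions) {
  f <- as.numeric(segment_fractions)
  if (length(f) < 1L) stop("at least one segment required", call. = FALSE)
  if (any(f <= 0) || any(f > 1)) stop("segment fractions must be in (0, 1]", call. = FALSE)
  if (length(f) > 1L && any(diff(f) >= 0))
    stop("segment fractions must be strictly decreasing", call. = FALSE)
  out <- c(-diff(f), f[length(f)])
  names(out) <- names(segment_fractions)
  out
}

#' Feed solution
#'
#' One inlet solution of the chemostat: its fresh-volume `segment_fraction`
#' per cycle, the concentration factor of its stock relative to nominal final
#' concentrations (`stock_multiplier`), and the nominal final levels of the
#' species it carries. The invariant `segment_fraction * stock_multiplier =
#' replaced_fraction` makes the no-reaction steady state of every fed species
#' equal its nominal level.
#'
#' @param name solution name (e.g. "energy", "protein", "dna").
#' @param segment_fraction fresh-volume fraction contributed per cycle.
#' @param stock_multiplier stock concentration / nominal final concentration.
#' @param species_levels named numeric vector of nominal final levels.
#' @return Object of class `feed_solution`.
#' @examples
#' feed_solution("energy", 0.08, 2.5, c(R = 1))
#' @export
feed_solution <- function(name, segment_fraction, stock_multiplier,
                          species_levels = numeric(0)) {
  if (segment_fraction <= 0 || segment_fraction >= 1)
    stop("segment_fraction must be in (0, 1)", call. = FALSE)
  if (stock_multiplier <= 0) stop("stock_multiplier must be > 0", call. = FALSE)
  species_levels <- unlist(species_levels)
  if (length(species_levels) && (is.null(names(species_levels)) ||
                                 any(!nzchar(names(species_levels)))))
    stop("species_levels must be named", call. = FALSE)
  if (any(species_levels < 0)) stop("species levels must be >= 0", call. = FALSE)
  structure(list(name = as.character(name),
                 segment_fraction = segment_fraction,
                 stock_multiplier = stock_multiplier,
                 species_levels = species_levels),
            class = "feed_solution")
}

validate_feed_set <- function(feeds, schedule, tol = 1e-9) {
  stopifnot(inherits(schedule, "dilution_schedule"))
  fr <- vapply(feeds, function(f) f$segment_fraction, numeric(1))
  if (abs(sum(fr) - schedule$replaced_fraction) > tol)
    stop("feed segment fractions must sum to the replaced fraction", call. = FALSE)
  for (f in feeds) {
    if (abs(f$segment_fraction * f$stock_multiplier - schedule$replaced_fraction) > tol)
      stop(sprintf("feed '%s': segment_fraction * stock_multiplier must equal replaced_fraction",
                   f$name), call. = FALSE)
  }
  invisible(feeds)
}

#' Canonical three-solution feed set
#'
#' Builds the energy / protein / DNA feed triple from the canonical segment
#' geometry [0.20, 0.12, 0.04] (fresh contributions 8%/8%/4%, stocks at
#' 2.5x/2.5x/5x nominal). Nominal levels: the energy solution carries the
#' resource; the protein solution carries the polymerase protein (full PURE)
#' or nothing (delta-PURE); the DNA solution carries both templates.
#'
#' @param d_T,d_G nominal DNA template levels in the DNA solution.
#' @param p_T nominal polymerase protein level in the protein solution
#'   (0 for a delta-PURE feed).
#' @param R nominal resource level in the energy solution.
#' @param tracer nominal tracer level in the protein solution (used by the
#'   synthetic-data layer; ignored by the mechanistic state).
#' @param schedule a [dilution_schedule()].
#' @param segments ordered segment fractions (strictly decreasing).
#' @return List of three [feed_solution()] objects.
#' @examples
#' canonical_feeds(d_T = 0.2, p_T = 1)
#' @export
canonical_feeds <- function(d_T = 0, d_G = 1, p_T = 0, R = 1, tracer = p_T,
                            schedule = dilution_schedule(),
                            segments = c(0.20, 0.12, 0.04)) {
  contrib <- segment_composition(segments)
  stocks <- schedule$replaced_fraction / contrib
  protein_levels <- c(p_T = p_T)
  if (tracer > 0 || p_T > 0) protein_levels <- c(protein_levels, tracer = tracer)
  feeds <- list(
    feed_solution("energy", contrib[1], stocks[1], c(R = R)),
    feed_solution("protein", contrib[2], stocks[2], protein_levels),
    feed_solution("dna", contrib[3], stocks[3], c(d_T = d_T, d_G = d_G))
  )
  validate_feed_set(feeds, schedule)
  feeds
}

#' Phase protocol
#'
#' Ordered, contiguous schedule of named phases with their feed sets,
#' starting at time 0 (minutes).
#'
#' @param phases list of phases, each `list(name, start, end, feeds)` with
#'   times in minutes and `feeds` a list of [feed_solution()] objects.
#' @return Object of class `phase_protocol`.
#' @seealso [canonical_protocol()]
#' @export
phase_protocol <- function(phases) {
  if (!length(phases)) stop("protocol needs at least one phase", call. = FALSE)
  starts <- vapply(phases, function(p) p$start, numeric(1))
  ends <- vapply(phases, function(p) p$end, numeric(1))
  if (starts[1] != 0) stop("first phase must start at 0", call. = FALSE)
  if (any(ends <= starts)) stop("each phase must end after it starts", call. = FALSE)
  if (length(phases) > 1L && any(abs(starts[-1] - ends[-length(ends)]) > 1e-9))
    stop("phases must be contiguous and non-overlapping", call. = FALSE)
  structure(list(phases = phases), class = "phase_protocol")
}

#' @export
print.phase_protocol <- function(x, ...) {
  cat("Phase protocol:\n")
  for (p in x$phases) {
    fed <- unlist(lapply(p$feeds, function(f) {
      lv <- f$species_levels
      lv <- lv[lv > 0]
      if (length(lv)) paste0(names(lv), "=", signif(lv, 3)) else NULL
    }))
    cat(sprintf("  %-18s [%5g, %5g) min  feeds: %s\n", p$name, p$start, p$end,
                if (length(fed)) paste(fed, collapse = ", ") else "(diluent only)"))
  }
  invisible(x)
}

protocol_end <- function(protocol) {
  ph <- protocol$phases
  ph[[length(ph)]]$end
}

phase_at <- function(protocol, t) {
  for (p in protocol$phases) {
    if (t >= p$start && t < p$end) return(p)
  }
  last <- protocol$phases[[length(protocol$phases)]]
  if (abs(t - last$end) < 1e-9) return(last)
  stop(sprintf("time %g min not covered by the protocol", t), call. = FALSE)
}

#' Canonical three-phase experiment protocol
#'
#' Builds the kick-start / self-regeneration / washout protocol for one of
#' the three experiment roles:
#' \describe{
#'   \item{`"sr"`}{self-regeneration: full PURE (polymerase fed) plus both DNA
#'     templates during kick-start; delta-PURE (no polymerase) with both
#'     templates during self-regeneration; polymerase DNA withheld during
#'     washout.}
#'   \item{`"pc"`}{positive control: full PURE and reporter DNA only, in all
#'     phases.}
#'   \item{`"nc"`}{negative control: as `"sr"` but with no polymerase DNA in
#'     any phase.}
#' }
#' Phase switches default to 4 h and 16 h. If `t_end` does not reach a
#' switch, later phases are dropped (e.g. a long-run experiment that omits
#' washout).
#'
#' @param role `"sr"`, `"pc"` or `"nc"`.
#' @param d_T polymerase DNA template level for the SR experiment.
#' @param d_G reporter DNA template level (all experiments).
#' @param p_T_feed polymerase protein level in the full-PURE protein feed.
#' @param R_feed resource level in the energy feed.
#' @param t_switch numeric length 2: phase-switch times in minutes.
#' @param t_end protocol end time in minutes.
#' @param schedule a [dilution_schedule()].
#' @param segments ordered segment fractions, see [canonical_feeds()].
#' @return A [phase_protocol()].
#' @examples
#' canonical_protocol("sr", d_T = 0.2)
#' @export
canonical_protocol <- function(role = c("sr", "pc", "nc"), d_T = 0.2, d_G = 1,
                               p_T_feed = 1, R_feed = 1,
                               t_switch = c(240, 960), t_end = 1200,
                               schedule = dilution_schedule(),
                               segments = c(0.20, 0.12, 0.04)) {
  role <- match.arg(role)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  mk <- function(d_T, p_T) canonical_feeds(d_T = d_T, d_G = d_G, p_T = p_T,
                                           R = R_feed, schedule = schedule,
                                           segments = segments)
  feeds3 <- switch(role,
    sr = list(mk(d_T, p_T_feed), mk(d_T, 0), mk(0, 0)),
    pc = list(mk(0, p_T_feed), mk(0, p_T_feed), mk(0, p_T_feed)),
    nc = list(mk(0, p_T_feed), mk(0, 0), mk(0, 0)))
  bounds <- c(0, t_switch, Inf)
  names3 <- c("kick-start", "self-regeneration", "washout")
  phases <- list()
  for (i in 1:3) {
    s <- bounds[i]; e <- min(bounds[i + 1], t_end)
    if (s >= t_end) break
    phases[[length(phases) + 1L]] <- list(name = names3[i], start = s, end = e,
                                          feeds = feeds3[[i]])
  }
  phase_protocol(phases)
}

#' Apply one discrete dilution event
#'
#' Replaces the feed fractions of the reactor volume: every species is
#' diluted by `(1 - F)` where `F` is the total replaced fraction, and each
#' feed solution adds `segment_fraction * stock_multiplier * nominal level`
#' of the species it carries. Species absent from all feeds are simply
#' diluted.
#'
#' @param state named nonnegative state vector.
#' @param feeds list of [feed_solution()] objects active for this cycle.
#' @return Post-dilution state vector.
#' @examples
#' s <- txtl_state(d_G = 1, p_G = 1, R = 1)
#' apply_dilution(s, canonical_feeds())
#' @export
apply_dilution <- function(state, feeds) {
  if (any(state < 0)) stop("state components must be >= 0", call. = FALSE)
  fr <- vapply(feeds, function(f) f$segment_fraction, numeric(1))
  F_tot <- sum(fr)
  if (F_tot >= 1) stop("total feed fraction must be < 1", call. = FALSE)
  out <- (1 - F_tot) * state
  for (f in feeds) {
    lv <- f$species_levels
    hit <- intersect(names(lv), names(out))
    if (length(hit))
      out[hit] <- out[hit] + f$segment_fraction * f$stock_multiplier * lv[hit]
  }
  out
}

#' Nominal reactor composition of a feed set
#'
#' The no-reaction steady state of a feed set: every fed species at its
#' nominal level, everything else 0. Used as the default initial condition
#' (the reactor is loaded with the first phase's composition at t = 0).
#'
#' @param feeds list of [feed_solution()] objects.
#' @return Named state vector of length 7 in canonical order.
#' @export
nominal_state <- function(feeds) {
  s <- stats::setNames(numeric(7), .STATE_NAMES)
  for (f in feeds) {
    hit <- intersect(names(f$species_levels), names(s))
    s[hit] <- f$species_levels[hit]
  }
  s
}

kernel_function <- function(kernel) {
  if (is.function(kernel)) return(kernel)
  switch(match.arg(kernel, c("resource_dependent", "resource_independent")),
         resource_dependent = resource_dependent_rhs,
         resource_independent = resource_independent_rhs)
}

#' Run a chemostat experiment
#'
#' Event-driven simulation of the reactor: each cycle starts with an
#' instantaneous dilution event using the feed set of the phase in force,
#' followed by continuous integration of the reaction kernel over one cycle
#' interval with an adaptive, stiffness-switching solver
#' (\code{deSolve::ode}, lsoda). The state is sampled on the cycle grid
#' `{0, dt, 2 dt, ...}` minutes (the value recorded at time `t > 0` is the
#' state at the end of the cycle, before the next replacement — the imaging
#' convention of the experiment). Small negative excursions (above `-1e-9`)
#' are clipped to 0; larger ones abort with the offending cycle index.
#'
#' @param params a [txtl_params()] object.
#' @param protocol a [phase_protocol()], e.g. from [canonical_protocol()].
#' @param schedule a [dilution_schedule()].
#' @param initial_state named length-7 state; default: the nominal
#'   composition of the first phase's feeds.
#' @param t_end end time in minutes (multiple of the cycle interval);
#'   default: the protocol end.
#' @param kernel `"resource_dependent"`, `"resource_independent"`, or a
#'   function `(state, params) -> derivatives`.
#' @param rtol,atol solver tolerances.
#' @return A `txtl_trace`: a data frame with `time_min`, the seven species
#'   columns in canonical order, and `phase`; attributes carry the schedule,
#'   parameters and kernel name.
#' @examples
#' tr <- run_chemostat(txtl_params(), canonical_protocol("pc", t_end = 120))
#' head(tr)
#' @export
run_chemostat <- function(params, protocol, schedule = dilution_schedule(),
                          initial_state = NULL, t_end = NULL,
                          kernel = "resource_dependent",
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "txtl_params"), inherits(protocol, "phase_protocol"),
            inherits(schedule, "dilution_schedule"))
  rhs <- kernel_function(kernel)
  kernel_name <- if (is.character(kernel)) kernel else "custom"
  dt <- schedule$cycle_interval
  if (is.null(t_end)) t_end <- protocol_end(protocol)
  n_cycles <- round(t_end / dt)
  if (abs(n_cycles * dt - t_end) > 1e-9 || n_cycles < 1L)
    stop("t_end must be a positive multiple of the cycle interval", call. = FALSE)
  if (protocol_end(protocol) < t_end - 1e-9)
    stop("protocol does not cover [0, t_end)", call. = FALSE)
  y <- if (is.null(initial_state)) nominal_state(protocol$phases[[1]]$feeds)
       else {
         check_state(initial_state)
         stats::setNames(as.numeric(initial_state), .STATE_NAMES)
       }
  ode_fun <- function(t, y, p) list(rhs(pmax(y, 0), p))
  out <- matrix(NA_real_, nrow = n_cycles + 1L, ncol = 7L,
                dimnames = list(NULL, .STATE_NAMES))
  out[1L, ] <- y
  times <- seq(0, t_end, by = dt)
  for (i in seq_len(n_cycles)) {
    t0 <- times[i]
    y <- apply_dilution(y, phase_at(protocol, t0)$feeds)
    sol <- deSolve::ode(y = y, times = c(0, dt), func = ode_fun, parms = params,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("ODE solver failed in cycle %d (t = %g min)", i, t0), call. = FALSE)
    y <- sol[2L, -1L]
    if (any(y < -1e-9))
      stop(sprintf("negative state beyond tolerance in cycle %d (min = %.3g)",
                   i, min(y)), call. = FALSE)
    y <- pmax(y, 0)
    names(y) <- .STATE_NAMES
    out[i + 1L, ] <- y
  }
  phase_lbl <- vapply(times, function(t) phase_at(protocol, t)$name, character(1))
  new_trace(data.frame(time_min = times, out, phase = phase_lbl,
                       check.names = FALSE),
            schedule = schedule, params = params, kernel = kernel_name)
}
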