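# Independent oracles and shared fixtures. The oracles deliberately avoid the
# package's own code paths: fixed-step explicit Euler instead of the adaptive
# solver, an exhaustive double loop instead of the vectorized dominance check.

# fixed-step explicit Euler integration of a kernel (no dilution events)
euler_integrate <- function(state, params, t_total, dt = 0.001,
                            rhs = resource_dependent_rhs) {
  y <- state
  for (i in seq_len(round(t_total / dt))) {
    y <- y + dt * rhs(pmax(y, 0), params)
  }
  y
}

# exhaustive O(n^2) Pareto dominance check (maximize both coordinates)
pareto_oracle <- function(df) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    dominated <- FALSE
    for (j in seq_len(nrow(df))) {
      if (j == i) next
      if (df$yield[j] >= df$yield[i] && df$robustness[j] >= df$robustness[i] &&
          (df$yield[j] > df$yield[i] || df$robustness[j] > df$robustness[i])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  df[keep, , drop = FALSE]
}

random_state <- function() {
  txtl_state(d_T = runif(1, 0, 2), d_G = runif(1, 0, 2),
             m_T = runif(1, 0, 1), m_G = runif(1, 0, 1),
             p_T = runif(1, 0, 2), p_G = runif(1, 0, 2),
             R = runif(1, 0.01, 2))
}

# memoized canonical simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())

cached_run <- function(role, d_T = 0, t_end = 1200, kernel = "resource_dependent") {
  key <- paste(role, d_T, t_end, kernel, sep = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- run_chemostat(
      txtl_params(),
      canonical_protocol(role, d_T = d_T, t_end = t_end),
      t_end = t_end, kernel = kernel)
  }
  .sim_cache[[key]]
}

# flat trace on the canonical grid, for constructed-bundle tests
flat_trace <- function(level, t_end = 1200) {
  parametric_trace(list(list(until = t_end, mode = "hold")), initial = level)
}

# deterministic per-seed starting guess within 2x of the true parameters
with_seed_guess <- function(seed, true_vec) {
  set.seed(seed + 1000)
  true_vec * exp(runif(length(true_vec), log(0.5), log(2)))
}
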