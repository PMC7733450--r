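test_that("noise-free bundles equal the raw simulation exactly", {
  quiet <- noise_model(relative_sd = 0, background_offset = 0,
                       background_drift = 0, seed = 5)
  b <- simulate_experiment(d_T = 0.1, noise = quiet, t_end = 480,
                           t_switch = c(240, 420))
  raw <- run_chemostat(txtl_params(),
                       canonical_protocol("sr", d_T = 0.1, t_end = 480,
                                          t_switch = c(240, 420)),
                       t_end = 480)
  expect_identical(b$sr[[1]]$p_G, raw$p_G)
  # and analysis metrics computed on both are identical
  expect_equal(yield_metric(b$sr[[1]], window = c(300, 420)),
               yield_metric(raw, window = c(300, 420)), tolerance = 1e-12)
})

test_that("equal seeds reproduce identical bundles, different seeds do not", {
  b1 <- simulate_experiment(d_T = 0.1, noise = noise_model(seed = 42),
                            t_end = 480, t_switch = c(240, 420))
  b2 <- simulate_experiment(d_T = 0.1, noise = noise_model(seed = 42),
                            t_end = 480, t_switch = c(240, 420))
  b3 <- simulate_experiment(d_T = 0.1, noise = noise_model(seed = 43),
                            t_end = 480, t_switch = c(240, 420))
  expect_identical(b1$sr[[1]]$p_G, b2$sr[[1]]$p_G)
  expect_identical(b1$pc$p_G, b2$pc$p_G)
  expect_false(identical(b1$sr[[1]]$p_G, b3$sr[[1]]$p_G))
})

test_that("background offset and drift shift the observed fluorescence", {
  n <- noise_model(relative_sd = 0, background_offset = 0.05,
                   background_drift = 0.01, seed = 1)
  b <- simulate_experiment(d_T = 0.1, noise = n, t_end = 480,
                           t_switch = c(240, 420))
  raw <- run_chemostat(txtl_params(),
                       canonical_protocol("sr", d_T = 0.1, t_end = 480,
                                          t_switch = c(240, 420)),
                       t_end = 480)
  expected <- raw$p_G + 0.05 + 0.01 * raw$time_min / 60
  expect_equal(b$sr[[1]]$p_G, expected, tolerance = 1e-12)
})

test_that("the tracer follows full-PURE feed presence under pure dilution", {
  quiet <- noise_model(relative_sd = 0, seed = 1)
  b <- simulate_experiment(d_T = 0.1, noise = quiet)
  # positive control: full PURE in all phases, tracer pinned at nominal
  expect_equal(b$pc$tracer, rep(1, nrow(b$pc)), tolerance = 1e-12)
  # self-regeneration: tracer at nominal through kick-start, then washes out
  tr <- b$sr[[1]]$tracer
  t <- b$sr[[1]]$time_min
  expect_equal(tr[t <= 240], rep(1, sum(t <= 240)), tolerance = 1e-12)
  after <- tr[t >= 240]
  expect_equal(after[-1] / after[-length(after)],
               rep(0.8, length(after) - 1), tolerance = 1e-9)
})

test_that("negative-control synthesis ceases early in the simulated bundle", {
  quiet <- noise_model(relative_sd = 0, seed = 1)
  b <- simulate_experiment(d_T = 0.1, noise = quiet)
  rate <- synthesis_rate(b$nc)
  kick_max <- max(rate[b$nc$time_min < 240], na.rm = TRUE)
  expect_lt(rate[b$nc$time_min == 960], 0.1 * kick_max)
})

test_that("parametric traces realize their segment shapes exactly", {
  # rise to a plateau
  tr <- parametric_trace(list(list(until = 300, mode = "linear", target = 1),
                              list(until = 600, mode = "hold")))
  expect_equal(trace_value_at(tr, 150), 0.5)
  expect_equal(trace_value_at(tr, 300), 1)
  expect_equal(trace_value_at(tr, 600), 1)
  # dilute mode reproduces the per-cycle factor
  tr2 <- parametric_trace(list(list(until = 150, mode = "dilute")), initial = 2)
  expect_equal(tr2$p_G, 2 * 0.8^(0:10))
  # phase labels follow the canonical switches
  tr3 <- flat_trace(1)
  expect_equal(unique(tr3$phase[tr3$time_min < 240]), "kick-start")
  expect_equal(unique(tr3$phase[tr3$time_min >= 960]), "washout")
  expect_error(parametric_trace(list(list(until = 7, mode = "hold"))), "grid")
  expect_error(parametric_trace(list(list(until = 300, mode = "hold"),
                                     list(until = 150, mode = "hold"))),
               "increasing")
})

test_that("parameters are recovered exactly from a noise-free bundle", {
  truth <- txtl_params()
  quiet <- noise_model(relative_sd = 0, seed = 1)
  b <- simulate_experiment(params = truth, d_T = c(0.05, 0.2, 1),
                           noise = quiet, t_end = 960, t_switch = c(240, 960))
  fit <- recover_parameters(b, initial_guess = truth, rtol = 1e-8)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimate / c(truth$alpha, truth$beta, truth$K) - 1)), 1e-6)
})

test_that("recovery error grows with the measurement noise level", {
  truth <- txtl_params()
  guess <- txtl_params(alpha = 0.15, beta = 0.07, K = 0.15)
  err_at <- function(sd) {
    b <- simulate_experiment(params = truth, d_T = c(0.05, 0.2, 1),
                             noise = noise_model(relative_sd = sd, seed = 99),
                             t_end = 960, t_switch = c(240, 960))
    fit <- recover_parameters(b, initial_guess = guess)
    max(abs(fit$estimate / c(truth$alpha, truth$beta, truth$K) - 1))
  }
  errs <- vapply(c(0, 0.02, 0.1), err_at, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[1], 1e-3)
})
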