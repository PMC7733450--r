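test_that("dilution rate, dilution time and residence time follow the closed forms", {
  mu <- dilution_rate(0.2, 15)
  expect_equal(mu, -log(0.8) / 15)
  expect_equal(mu, 0.014876, tolerance = 1e-4)
  expect_equal(round(dilution_time(mu)), 47)           # the ~47 min half-life
  expect_equal(residence_time(mu), 15 / -log(0.8))
  expect_equal(dilution_rate(0.5, log(2)), 1)
  expect_equal(dilution_time(log(2)), 1)
  # vanishing replacement -> vanishing rate
  expect_lt(dilution_rate(1e-9, 15), 1e-9)
  expect_error(dilution_rate(1.2, 15), "replaced_fraction")
  expect_error(dilution_time(0), "rate")
})

test_that("sequential segment loading yields the overwrite composition", {
  expect_equal(unname(segment_composition(c(0.20, 0.12, 0.04))),
               c(0.08, 0.08, 0.04))
  expect_equal(segment_composition(0.15), 0.15)
  expect_equal(unname(segment_composition(c(0.3, 0.1))), c(0.2, 0.1))
  expect_equal(sum(segment_composition(c(0.20, 0.12, 0.04))), 0.20)
  expect_error(segment_composition(c(0.1, 0.2)), "decreasing")
})

test_that("dilution events mix feeds at stock x segment and dilute the rest", {
  feeds <- canonical_feeds(d_T = 0, d_G = 1, p_T = 0, R = 1)
  # fed species at nominal level is a fixed point (5x DNA stock through 4%)
  s <- txtl_state(d_G = 1, R = 1)
  s2 <- apply_dilution(s, feeds)
  expect_equal(s2[["d_G"]], 1)
  expect_equal(s2[["R"]], 1)
  # unfed species is diluted by (1 - F)
  s3 <- apply_dilution(txtl_state(p_G = 1), feeds)
  expect_equal(s3[["p_G"]], 0.8)
  # state identical to full feed composition is unchanged
  full <- canonical_feeds(d_T = 0.5, d_G = 1, p_T = 1, R = 1)
  sn <- nominal_state(full)
  expect_equal(apply_dilution(sn, full), sn)
  # invalid geometry is rejected
  expect_error(apply_dilution(s, list(feed_solution("x", 0.6, 1.5, c(R = 1)),
                                      feed_solution("y", 0.5, 1.2, c(R = 1)))),
               "< 1")
})

test_that("feed sets enforce the stock/segment bookkeeping", {
  sched <- dilution_schedule()
  feeds <- canonical_feeds()
  fr <- vapply(feeds, function(f) f$segment_fraction, numeric(1))
  expect_equal(sum(fr), sched$replaced_fraction)
  for (f in feeds)
    expect_equal(f$segment_fraction * f$stock_multiplier, sched$replaced_fraction)
  expect_equal(vapply(feeds, function(f) f$stock_multiplier, numeric(1)),
               c(2.5, 2.5, 5))
  bad <- list(feed_solution("energy", 0.1, 2.5, c(R = 1)))
  expect_error(pureregen:::validate_feed_set(bad, sched), "sum")
})

test_that("inert chemistry dilutes unfed species as (1-F)^n on the exact grid", {
  zero_kernel <- function(state, params) stats::setNames(numeric(7), names(state))
  proto <- canonical_protocol("nc", t_end = 150)
  init <- nominal_state(proto$phases[[1]]$feeds)
  init[["p_G"]] <- 1
  tr <- run_chemostat(txtl_params(), proto, initial_state = init,
                      t_end = 150, kernel = zero_kernel)
  expect_identical(tr$time_min, seq(0, 150, by = 15))
  expect_equal(tr$p_G, 0.8^(0:10), tolerance = 1e-12)
  # fed, non-reacting species converge geometrically to nominal: the error
  # shrinks by (1-F) per cycle, i.e. halves every dilution time t_d
  init2 <- init
  init2[["R"]] <- 0
  tr2 <- run_chemostat(txtl_params(), proto, initial_state = init2,
                       t_end = 150, kernel = zero_kernel)
  err <- abs(tr2$R - 1)
  expect_equal(err[-1] / err[-length(err)], rep(0.8, 10), tolerance = 1e-9)
})

test_that("adaptive integration matches a fine-step Euler oracle over one cycle", {
  p <- txtl_params()
  proto <- canonical_protocol("sr", d_T = 0.2)
  feeds <- proto$phases[[1]]$feeds
  # a mid-experiment composition with all components at moderate levels, so
  # every species stays well scaled within the cycle
  y0 <- txtl_state(d_T = 0.2, d_G = 1, m_T = 0.05, m_G = 0.3,
                   p_T = 0.1, p_G = 0.2, R = 1)
  tr <- run_chemostat(p, proto, initial_state = y0, t_end = 15)
  y_euler <- euler_integrate(apply_dilution(y0, feeds), p, t_total = 15, dt = 0.001)
  y_pkg <- unlist(tr[2, names(y0)])
  expect_lt(max(abs(y_pkg - y_euler) / pmax(abs(y_euler), 1e-12)), 1e-3)
})

test_that("conserved quantity drifts below 1e-8 over a 4 h inter-dilution integration", {
  p <- txtl_params()
  s0 <- txtl_state(d_T = 0.2, d_G = 1, p_T = 1, R = 1)
  fn <- function(t, y, pp) list(resource_dependent_rhs(pmax(y, 0), pp))
  sol <- deSolve::ode(s0, seq(0, 240, by = 15), fn, p,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  tot <- rowSums(sol[, c("m_T", "m_G", "p_T", "p_G", "R")])
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
  # resource is monotone non-increasing while synthesis runs (up to the
  # solver's absolute tolerance once R is effectively exhausted)
  expect_true(all(diff(sol[, "R"]) <= 1e-10))
  # everything stays nonnegative
  expect_true(all(sol[, -1] >= -1e-12))
})

test_that("negative control loses synthesis activity after the kick-start", {
  nc <- cached_run("nc")
  rate <- synthesis_rate(nc)
  kick_max <- max(rate[nc$time_min < 240], na.rm = TRUE)
  late <- rate[nc$time_min == 960]
  expect_lt(late, 0.1 * kick_max)
  # the reporter itself decays toward zero at the end of the run
  expect_lt(nc$p_G[nrow(nc)], 0.05 * max(nc$p_G))
})

test_that("run_chemostat validates protocol coverage and timing", {
  p <- txtl_params()
  proto <- canonical_protocol("pc", t_end = 120)
  expect_error(run_chemostat(p, proto, t_end = 100), "multiple")
  expect_error(run_chemostat(p, proto, t_end = 300), "cover")
  tr <- run_chemostat(p, proto, t_end = 120)
  expect_s3_class(tr, "txtl_trace")
  expect_named(tr, c("time_min", "d_T", "d_G", "m_T", "m_G", "p_T", "p_G",
                     "R", "phase"))
})
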