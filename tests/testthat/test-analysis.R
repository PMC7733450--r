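test_that("bundles normalize to the positive-control maximum with global fallback", {
  pc <- flat_trace(0)
  pc$p_G <- 5 * sin(pi * pc$time_min / max(pc$time_min))  # PC peaking at 5
  sr <- flat_trace(2)
  b <- normalize_to_pc(experiment_bundle(list(a = sr), pc = pc))
  expect_equal(max(b$pc$p_G), 1)
  expect_equal(b$normalization, 5)
  expect_equal(b$sr$a$p_G, rep(2 / 5, nrow(sr)))
  # without a PC the overall maximum is the reference
  b2 <- normalize_to_pc(experiment_bundle(list(a = flat_trace(3), b = flat_trace(1))))
  expect_equal(b2$normalization, 3)
  expect_equal(max(b2$sr$a$p_G), 1)
  # an all-zero SR trace stays all-zero
  b3 <- normalize_to_pc(experiment_bundle(list(z = flat_trace(0)), pc = pc))
  expect_true(all(b3$sr$z$p_G == 0))
  # all-zero reference is degenerate
  expect_error(normalize_to_pc(experiment_bundle(list(z = flat_trace(0)))),
               "degenerate")
})

test_that("synthesis rate removes the known dilution", {
  sched <- dilution_schedule()
  # steady level: synthesis exactly balances dilution, rate = F c / dt
  tr <- flat_trace(0.6, t_end = 300)
  r <- synthesis_rate(tr, sched)
  expect_equal(r[-length(r)], rep(0.2 * 0.6 / 15, length(r) - 1))
  expect_true(is.na(r[length(r)]))
  # pure dilution: zero inferred production
  dec <- parametric_trace(list(list(until = 300, mode = "dilute")), initial = 1)
  expect_equal(synthesis_rate(dec, sched)[1:19], rep(0, 19), tolerance = 1e-15)
  # zero trace: zero rates
  expect_equal(synthesis_rate(flat_trace(0, 300), sched)[1:19], rep(0, 19))
  # non-uniform grids are rejected
  bad <- as.data.frame(flat_trace(1, 300))[c(1, 3, 4), ]
  expect_error(synthesis_rate(bad, sched), "uniform")
})

test_that("SR/PC ratio compares traces at the titration timepoint", {
  pc <- flat_trace(0.8)
  b <- experiment_bundle(list(same = flat_trace(0.8), half = flat_trace(0.4)),
                         pc = pc)
  r <- sr_pc_ratio(b)                      # default 15 h
  expect_equal(unname(r), c(1, 0.5))
  expect_equal(unname(sr_pc_ratio(b, at_time = 300)), c(1, 0.5))
  expect_error(sr_pc_ratio(b, at_time = 301), "grid")
  expect_error(sr_pc_ratio(experiment_bundle(list(a = flat_trace(1)),
                                             pc = flat_trace(0)),
                           at_time = 300), "degenerate")
})

test_that("regeneration duration measures sustained synthesis beyond the negative control", {
  nc <- flat_trace(0)
  # SR identical to the negative control: zero duration
  expect_equal(regeneration_duration(flat_trace(0), nc), 0)
  # plateau for 10 h after SR start, then pure washout decay: duration 10 h
  sr10 <- parametric_trace(list(list(until = 840, mode = "hold"),
                                list(until = 1200, mode = "dilute")),
                           initial = 1)
  expect_equal(regeneration_duration(sr10, nc), 10, tolerance = 0.03)
  # sustained through a 26 h self-regeneration phase scores >= 24 h
  long_nc <- flat_trace(0, t_end = 1800)
  long_sr <- flat_trace(1, t_end = 1800)
  expect_gte(regeneration_duration(long_sr, long_nc), 24)
  # mismatched grids are rejected
  expect_error(regeneration_duration(sr10, long_nc), "common")
})

test_that("robustness is duration/24 h, capped at 1 and monotone", {
  expect_identical(robustness(26), 1)
  expect_identical(robustness(24), 1)
  expect_equal(robustness(12), 0.5)
  expect_identical(robustness(0), 0)
  d <- seq(0, 48, by = 0.5)
  r <- robustness(d)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r[d >= 24] == 1))
  expect_true(all(r >= 0 & r <= 1))
  expect_error(robustness(-1), ">= 0")
})

test_that("yield averages the normalized reporter over the late self-regeneration window", {
  expect_equal(yield_metric(flat_trace(1)), 1)
  expect_equal(yield_metric(flat_trace(0.4)), 0.4)
  # same trace as PC over any shared window
  tr <- flat_trace(0.73)
  expect_equal(yield_metric(tr, window = c(300, 600)),
               yield_metric(tr, window = c(700, 900)))
  expect_error(yield_metric(flat_trace(1), window = c(2000, 3000)), "empty")
})

test_that("theoretical maximal yield allocates capacity by DNA fraction", {
  expect_equal(as.numeric(theoretical_max_yield(1, c(eGFP = 2))), 1)
  expect_equal(as.numeric(theoretical_max_yield(
    1, c(eGFP = 2, AsnRS = 0.5, LeuRS = 0.5, ArgRS = 0.5, TyrRS = 0.5))), 0.5)
  # ratio invariance under rescaling all inputs
  d <- c(eGFP = 2, A = 0.3, B = 0.7)
  expect_equal(as.numeric(theoretical_max_yield(1, d)),
               as.numeric(theoretical_max_yield(1, 2 * d)))
  expect_error(theoretical_max_yield(1, c(A = 1)), "reporter")
})

test_that("washout peaks need both an excess and a subsequent decline", {
  # monotone washout decay: no peak
  dec <- parametric_trace(list(list(until = 960, mode = "hold"),
                               list(until = 1320, mode = "dilute")),
                          initial = 1)
  expect_false(detect_washout_peak(dec)$present)
  # +10% bump one hour into washout, then decay below the starting level
  bump <- parametric_trace(list(list(until = 960, mode = "hold"),
                                list(until = 1020, mode = "linear", target = 1.1),
                                list(until = 1440, mode = "dilute")),
                           initial = 1)
  pk <- detect_washout_peak(bump)
  expect_true(pk$present)
  expect_equal(pk$time, 1020)
  expect_equal(pk$height, 1.1)
  # an excess that never declines again is not a transient peak
  rise <- parametric_trace(list(list(until = 960, mode = "hold"),
                                list(until = 1440, mode = "linear", target = 1.5)),
                           initial = 1)
  expect_false(detect_washout_peak(rise)$present)
  expect_error(detect_washout_peak(flat_trace(1, t_end = 1050)), "2 h")
})

test_that("pareto front equals the exhaustive dominance oracle", {
  pts <- data.frame(yield = c(0.9, 0.5, 0.95), robustness = c(1.0, 1.0, 0.2))
  expect_equal(pareto_front(pts), pts[c(1, 3), ])
  # a single point is its own front; duplicated optima are both retained
  expect_equal(pareto_front(pts[1, ]), pts[1, ])
  dup <- data.frame(yield = c(0.9, 0.9, 0.1), robustness = c(1, 1, 0.1))
  expect_equal(nrow(pareto_front(dup)), 2)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    df <- data.frame(yield = round(runif(n), 2), robustness = round(runif(n), 2))
    expect_equal(pareto_front(df), pareto_oracle(df))
  }
})

test_that("compute_metrics assembles one row per self-regeneration experiment", {
  b <- experiment_bundle(
    list(good = flat_trace(0.9),
         poor = parametric_trace(list(list(until = 480, mode = "hold"),
                                      list(until = 1200, mode = "dilute")),
                                 initial = 0.9)),
    pc = flat_trace(1), nc = flat_trace(0),
    dna_inputs = list(c(eGFP = 2, T7 = 0.5), c(eGFP = 2, T7 = 0.05)))
  m <- compute_metrics(b)
  expect_equal(nrow(m), 2)
  expect_true(all(c("yield", "robustness", "sr_pc_ratio", "washout_peak") %in% names(m)))
  expect_gt(m$yield[1], m$yield[2])
  expect_gt(m$robustness[1], m$robustness[2])
  expect_equal(m$sr_pc_ratio[1], 0.9)
})
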