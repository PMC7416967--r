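fake_traj <- function(x, dt = 0.5, t_max = 1800) {
  t <- seq(0, t_max, dt)
  data.frame(time = t, ca_cyt = x(t))
}

test_that("a constant trace is quiescent and a sinusoid is not", {
  flat <- fake_traj(function(t) rep(0.1, length(t)))
  o <- detect_oscillation(flat)
  expect_false(o$oscillatory)
  expect_equal(o$amplitude, 0)

  sine <- fake_traj(function(t) 0.1 + 0.05 * sin(2 * pi * t / 30))
  o <- detect_oscillation(sine)
  expect_true(o$oscillatory)
  expect_equal(o$amplitude, 0.05, tolerance = 1e-3)
  expect_equal(o$dominant_period, 30, tolerance = 1 / 30)
})

test_that("amplitude ignores offsets and the period ignores scale", {
  base <- function(t) 0.02 * sin(2 * pi * t / 45)
  o1 <- detect_oscillation(fake_traj(function(t) 0.1 + base(t)))
  o2 <- detect_oscillation(fake_traj(function(t) 5 + base(t)))
  o3 <- detect_oscillation(fake_traj(function(t) 0.1 + 10 * base(t)))
  expect_equal(o1$amplitude, o2$amplitude, tolerance = 1e-12)
  expect_equal(o1$dominant_period, o2$dominant_period)
  expect_equal(o1$dominant_period, o3$dominant_period)
})

test_that("period recovery survives 10% additive noise across 5-300 s", {
  set.seed(2024)
  for (per in c(5, 20, 60, 150, 300)) {
    tr <- fake_traj(function(t)
      0.1 + 0.05 * sin(2 * pi * t / per) +
        stats::rnorm(length(t), sd = 0.005))
    o <- detect_oscillation(tr)
    expect_true(o$oscillatory)
    expect_lt(abs(o$dominant_period - per) / per, 0.05)
  }
})

test_that("slow drift alone does not classify as oscillation", {
  drift <- fake_traj(function(t) 0.1 + 0.05 * t / 1800)
  o <- detect_oscillation(drift)
  expect_false(o$oscillatory)
})

test_that("period averaging uses whole cycles", {
  flat <- fake_traj(function(t) rep(0.37, length(t)))
  expect_equal(period_average(flat, "ca_cyt"), 0.37)
  # sinusoid about a known mean: whole-cycle average recovers the mean
  sine <- fake_traj(function(t) 0.2 + 0.1 * sin(2 * pi * t / 77))
  expect_equal(period_average(sine, "ca_cyt"), 0.2, tolerance = 1e-2)
  expect_error(period_average(sine, "nope"), "unknown observable")
})

test_that("classification of the reference scenario is sampling-stable", {
  m <- test_model()
  o1 <- detect_oscillation(simulate(m, ca_mit = 0.25, t_max = 1800,
                                    output_dt = 0.5))
  o2 <- detect_oscillation(simulate(m, ca_mit = 0.25, t_max = 1800,
                                    output_dt = 0.25))
  expect_identical(o1$oscillatory, o2$oscillatory)
  expect_equal(o1$dominant_period, o2$dominant_period, tolerance = 0.05)
  # baseline stays quiescent and period-averages to its resting value
  trb <- simulate(m, ca_mit = 0.1, t_max = 1800)
  ob <- detect_oscillation(trb)
  expect_false(ob$oscillatory)
  expect_equal(period_average(trb, "ca_cyt", osc = ob), 0.1,
               tolerance = 1e-6)
})
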