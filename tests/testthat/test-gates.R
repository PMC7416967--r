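test_that("cross-bridge subsystem conserves probability and has the known rest state", {
  p <- vsm_params()
  # fixed point at resting calcium, from an independent linear solve of the
  # full four-state system (M retained explicitly)
  K1 <- p$gamma_cross * 0.1^3
  A <- rbind(c(-K1, p$K4 - K1, -K1),            # dMp with M = 1 - sum
             c(p$K3, -(p$K4 + p$K5), K1),
             c(0, p$K5, -(p$K7 + K1)))
  A[1, 1] <- A[1, 1] - (p$K2 + p$K3)
  b <- c(K1, 0, 0)
  fp <- solve(A, -b)
  ms <- myosin_steady(0.1, p)
  expect_equal(unname(ms[c("Mp", "AMp", "AM")]), fp, tolerance = 1e-10)
  expect_equal(unname(ms["Mp"]), 0.018699, tolerance = 1e-4)
  expect_equal(unname(ms["AMp"]), 0.014183, tolerance = 1e-4)
  expect_equal(unname(ms["AM"]), 0.060612, tolerance = 1e-4)
  expect_equal(tension_fraction(ms), 0.074795, tolerance = 1e-4)

  # absorbing relaxed state at zero calcium
  expect_equal(unname(myosin_rhs(0, 0, 0, 0, p)), c(0, 0, 0))

  # conservation: the four state derivatives sum to zero for random states
  set.seed(42)
  for (i in 1:200) {
    x <- stats::runif(3); x <- x / sum(x) * stats::runif(1)
    d <- myosin_rhs(x[1], x[2], x[3], stats::runif(1, 0, 2), p)
    dM <- -sum(d)  # M eliminated; total must be stationary
    expect_lt(abs(sum(d) + dM), 1e-12)
  }
})

test_that("myosin calcium flux follows the phosphorylated-head bookkeeping", {
  p <- vsm_params()
  expect_equal(myosin_ca_flux(c(0.01, 0, 0), p), -0.1)  # Myo_tot = 10
  ms <- myosin_steady(0.1, p)
  d <- myosin_rhs(ms[["Mp"]], ms[["AMp"]], ms[["AM"]], 0.1, p)
  expect_equal(myosin_ca_flux(d, p), 0, tolerance = 1e-12)
  # net phosphorylation lowers free calcium
  expect_lt(myosin_ca_flux(c(0.02, 0.01, 0), p), 0)
})

test_that("IP3/PIP2 steady state solves the two-variable system", {
  p <- vsm_params()
  ss <- ip3_steady(0.1, p)
  expect_equal(ss[["ip3"]], 7.367876e-3, tolerance = 1e-6)
  d <- ip3_pip2_rhs(ss[["ip3"]], ss[["pip2"]], 0.1, p)
  expect_lt(max(abs(d)), 1e-12)
  # calcium-free limit: production stops
  expect_equal(unname(ip3_pip2_rhs(0.5, 100, 0, p))[1], -p$kdeg_IP3 * 0.5)
  p0 <- vsm_params(eta_IP3 = 1e-300)  # production effectively off
  ss0 <- ip3_steady(0.1, p0)
  expect_equal(ss0[["ip3"]], 0, tolerance = 1e-290)
})

test_that("IP3R reduction agrees with the explicit four-state generator", {
  p <- vsm_params()
  set.seed(7)
  for (i in 1:50) {
    ca <- stats::runif(1, 0.02, 2)
    ip3 <- stats::runif(1, 1e-3, 0.1)
    x <- stats::runif(4); x <- x / sum(x)
    Q <- ip3r_generator(ca, ip3, p)
    d_full <- as.numeric(t(Q) %*% x)          # X00, X01, X10, X11
    expect_lt(abs(sum(d_full)), 1e-12)
    d_red <- ip3r_rhs(x[1], x[2], x[3], ca, ip3, p)
    expect_equal(unname(d_red), d_full[1:3], tolerance = 1e-12)
  }
  expect_error(ip3r_rhs(0.5, 0.2, 0.1, 0.1, 0, p), "ip3")
})

test_that("RyR reduction agrees with the explicit four-state generator", {
  p <- vsm_params()
  set.seed(8)
  for (i in 1:50) {
    ca <- stats::runif(1, 0.02, 2)
    x <- stats::runif(4); x <- x / sum(x)   # R00, R10, R11, R01
    Q <- ryr_generator(ca, p)
    d_full <- as.numeric(t(Q) %*% x)
    expect_lt(abs(sum(d_full)), 1e-12)
    d_red <- ryr_rhs(x[2], x[3], x[4], ca, p)
    expect_equal(unname(d_red), d_full[2:4], tolerance = 1e-12)
  }
})

test_that("gate fixed points match the stationary distributions and are attracting", {
  p <- vsm_params()
  ip3 <- ip3_steady(0.1, p)[["ip3"]]
  gs <- gate_steady(0.1, p)

  pi_x <- stationary(ip3r_generator(0.1, ip3, p))
  expect_equal(unname(gs[c("X00", "X01", "X10", "X11")]), pi_x,
               tolerance = 1e-10)
  pi_r <- stationary(ryr_generator(0.1, p))
  expect_equal(unname(gs[c("R00", "R10", "R11", "R01")]), pi_r,
               tolerance = 1e-10)

  # detailed balance for the RyR square network
  r1 <- p$Kr1 * 0.1^2 / p$Kmr1
  r2 <- p$Kr2 * 0.1 / p$Kmr2
  expect_equal(gs[["R10"]] / gs[["R00"]], r1, tolerance = 1e-10)
  expect_equal(gs[["R01"]] / gs[["R00"]], r2, tolerance = 1e-10)
  expect_equal(gs[["R11"]] / gs[["R10"]], r2, tolerance = 1e-10)

  # all probabilities valid
  expect_true(all(gs >= 0 & gs <= 1))

  # both reduced systems are attracting at fixed (ca, ip3): eigenvalues of
  # the affine systems' matrices have negative real parts
  for (f in list(function(a, b, c.) ip3r_rhs(a, b, c., 0.1, ip3, p),
                 function(a, b, c.) ryr_rhs(a, b, c., 0.1, p))) {
    b0 <- f(0, 0, 0)
    A <- cbind(f(1, 0, 0) - b0, f(0, 1, 0) - b0, f(0, 0, 1) - b0)
    expect_true(all(Re(eigen(A, only.values = TRUE)$values) < 0))
  }
})
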