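test_that("MCU flux is unidirectional uptake with the expected magnitude", {
  p <- test_params()
  expect_identical(flux_mcu(0, p), 0)
  expect_equal(flux_mcu(0.1, p), -1.069667e-3, tolerance = 1e-6)
  grid <- 10^seq(-3, 1, length.out = 100)
  expect_true(all(flux_mcu(grid, p) <= 0))
  expect_gt(abs(flux_mcu(1, p)), abs(flux_mcu(0.1, p)))
})

test_that("NCLX flux is linear in matrix calcium and guarded at zero", {
  p <- test_params()
  expect_equal(flux_nclx(0.1, 0.1, p), 0.13 * exp(0.0161 * 140),
               tolerance = 1e-12)
  expect_equal(flux_nclx(0.1, 0.1, p), 1.23835, tolerance = 1e-5)
  expect_identical(flux_nclx(0.2, 0, p), 0)
  expect_equal(flux_nclx(0.1, 0.5, p), 2 * flux_nclx(0.1, 0.25, p))
  expect_error(flux_nclx(0, 0.1, p), "NCLX")
})

test_that("mitochondrial Nernst potential has the textbook properties", {
  p <- test_params()
  expect_identical(nernst_mit(0.1, 0.1, p), 0)
  expect_equal(nernst_mit(0.25, 0.1, p), 13.356 * log(2.5), tolerance = 1e-4)
  set.seed(3)
  a <- stats::runif(20, 0.01, 10); b <- stats::runif(20, 0.01, 10)
  expect_equal(nernst_mit(a, b, p), -nernst_mit(b, a, p))
  expect_error(nernst_mit(0, 0.1, p), "> 0")
})

test_that("calibrated mitochondrial leak balances MCU + NCLX at rest", {
  p <- test_params()
  expect_equal(p$nu_mit_leak, 8.83771e-3, tolerance = 1e-5)
  expect_equal(flux_mit_leak(0.1, 0.1, p), -p$nu_mit_leak * 140)
  total <- flux_mcu(0.1, p) + flux_nclx(0.1, 0.1, p) +
    flux_mit_leak(0.1, 0.1, p)
  expect_lt(abs(total), 1e-12)
  # leak vanishes when the Nernst potential equals the membrane potential
  cm <- 0.1 * exp(p$dPsi_m / p$RT_over_2F)
  expect_equal(flux_mit_leak(cm, 0.1, p), 0, tolerance = 1e-12)
})

test_that("SERCA reverses exactly at the thermodynamic ratio", {
  p <- test_params()
  ratio <- p$K1_serca * p$K3_serca *
    sqrt(p$km2_serca * p$km4_serca / (p$k2_serca * p$k4_serca))
  expect_equal(ratio, 5.416e-7, tolerance = 1e-3)
  cer <- 500
  expect_equal(flux_serca(ratio * cer, cer, p), 0, tolerance = 1e-15)
  # forward (pumping, negative) above the ratio; reverse below
  expect_lt(flux_serca(0.1, 500, p), 0)
  expect_gt(flux_serca(0, 500, p), 0)
})

test_that("release channel fluxes follow their open probabilities", {
  p <- test_params()
  b <- test_model()$baseline
  expect_equal(flux_ipr(b[["X10"]], 0.1, 500, p), 0.222052, tolerance = 1e-4)
  expect_equal(flux_ipr(1, 0.1, 500, p), p$nu_ipr * 499.9)   # Po = 1
  expect_identical(flux_ipr(0.3, 0.2, 0.2, p), 0)
  expect_equal(flux_ryr(b[["R10"]], 0.1, 500, p), 1.0710e-3,
               tolerance = 1e-3)
  expect_identical(flux_ryr(0, 0.1, 500, p), 0)
  expect_identical(flux_ryr(0.3, 0.7, 0.7, p), 0)
})

test_that("plasma-membrane fluxes match direct evaluation at rest", {
  p <- test_params()
  expect_equal(flux_vocc(0.1, p), 0.0212525, tolerance = 1e-5)
  pm <- flux_pm_leak_pmca(0.1, p)
  expect_equal(pm[["J_ecs_leak"]], 5.41570e-3, tolerance = 1e-5)
  expect_equal(pm[["J_pmca"]], -0.016)
  expect_equal(flux_pm_leak_pmca(1e-12, p)[["J_pmca"]], 0,
               tolerance = 1e-9)
  expect_equal(flux_ncx(0.1, p), -0.0106682, tolerance = 1e-4)
  # VOCC gate: logistic activation midpoint at 0 mV
  p0 <- test_params()
  p0$phi_ecs <- 0
  dbar <- 1 / (1 + exp(-p0$phi_ecs / 8.3))
  expect_equal(dbar, 0.5)
  # VOCC vanishes when held at the calcium Nernst potential
  c_rev <- p$Ca_ecs * exp(-p$phi_ecs / p$RT_over_2F)
  expect_equal(flux_vocc(c_rev, p), 0, tolerance = 1e-12)
  # NCX activation dies at low calcium, extrusion grows near rest
  expect_equal(flux_ncx(1e-9, p), 0, tolerance = 1e-12)
  cg <- seq(0.08, 0.3, by = 0.01)
  expect_true(all(diff(abs(flux_ncx(cg, p))) > 0))
})

test_that("ATP-equivalent rate is proportional to the matrix flux", {
  p <- test_params()
  expect_identical(atp_rate(0, p), 0)
  expect_equal(atp_rate(3, vsm_params(protons_per_Ca = 2,
                                      Q_ncx = 1, serca_scale = 1,
                                      nu_mit_leak = 1)), 2)
  expect_identical(sign(atp_rate(c(-1, 1), p)), c(-1, 1))
})

test_that("flux decomposition aggregates equal the sum of their parts", {
  m <- test_model()
  set.seed(11)
  for (i in 1:20) {
    st <- m$baseline
    st["ca_cyt"] <- stats::runif(1, 0.02, 2)
    st["ca_er"] <- stats::runif(1, 50, 2000)
    st[c("X10", "R10")] <- stats::runif(2, 0, 0.2)
    p <- m$params
    p$Ca_mit <- stats::runif(1, 0.05, 0.6)
    p$alpha_er <- stats::runif(1, 0.1, 10)
    p$alpha_mit <- stats::runif(1, 0.1, 10)
    p$alpha_pm <- stats::runif(1, 0.1, 10)
    fb <- flux_breakdown(st, p)
    expect_equal(fb$J_mit_to_cyt,
                 p$alpha_mit * (fb$J_mcu + fb$J_nclx + fb$J_mit_leak),
                 tolerance = 1e-12)
    expect_equal(fb$J_er_to_cyt,
                 p$alpha_er * (fb$J_serca + fb$J_ipr + fb$J_ryr),
                 tolerance = 1e-12)
    expect_equal(fb$J_ecs_to_cyt,
                 p$alpha_pm * (fb$J_ecs_leak + fb$J_pmca + fb$J_ncx +
                                 fb$J_vocc),
                 tolerance = 1e-12)
  }
})
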