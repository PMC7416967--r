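test_that("tissue envelope reproduces the acute-phase accounting", {
  # 1 mM -> 0.1 mM with the ECS volume halved: 95% of the calcium moves in
  env <- tissue_envelope(ecs_conc = 1000, residual_conc = 100,
                         volume_shrink = 0.5)
  expect_equal(env[["transfer_pct"]], 95)
  # 1.3 mM over a 20/80 split concentrates to 325 uM in the cells
  env2 <- tissue_envelope()
  expect_equal(env2[["effective_load"]], 325)
  expect_gt(env2[["effective_load"]], 300)
  # dilution-factor form agrees
  env3 <- tissue_envelope(dilution_factor = 4)
  expect_equal(env3[["effective_load"]], 325)
  expect_equal(tissue_envelope(ecs_conc = 0)[["transfer_pct"]], 0)
  expect_error(tissue_envelope(cell_fraction = 0), "> 0")
  expect_error(tissue_envelope(ecs_fraction = 0.5, cell_fraction = 0.8),
               "at most 1")
})

test_that("the onset scan brackets and refines a classification change", {
  m <- test_model()
  hs <- hopf_scan(m, ca_mit_range = c(0.2, 0.3), n_points = 3,
                  refine = TRUE, refine_width = 0.01)
  expect_s3_class(hs, "hopf_scan")
  expect_false(is.na(hs$threshold))
  expect_gt(hs$threshold, 0.2)
  expect_lt(hs$threshold, 0.3)
  expect_true(all(hs$grid$ca_min <= hs$grid$ca_mean))
  expect_true(all(hs$grid$ca_mean <= hs$grid$ca_max))
  # monotone classification over this bracket: quiescent below, oscillatory
  # at the top of the bracket
  expect_false(hs$grid$oscillatory[1])
})

test_that("the scan reports an absent threshold when nothing changes", {
  m <- test_model()
  hs <- hopf_scan(m, ca_mit_range = c(0.1, 0.15), n_points = 2,
                  refine = FALSE, t_max = 900)
  expect_true(is.na(hs$threshold))
})

test_that("the reference run reports the headline clearance quantities", {
  ref <- test_reference()
  expect_true(ref$oscillation$oscillatory)
  expect_gt(ref$clearance[["ca_sink"]], 0)
  expect_true(all(ref$tension_range >= 0 & ref$tension_range <= 1))
  expect_gt(ref$mean_J_mit_to_cyt, 0)   # net matrix emptying post-transient
  expect_equal(ref$mean_atp_rate,
               ref$mean_J_mit_to_cyt * 2 / 3, tolerance = 1e-9)
  expect_lt(ref$mass_balance_drift, 1e-4)
})

test_that("a small rescaling sweep is structurally sound", {
  m <- test_model()
  sw <- alpha_sweep(m, points_per_axis = 3, t_max = 900)
  expect_equal(nrow(sw$grid), 27)
  expect_false(any(sw$grid$failed))
  expect_gte(sw$inward_fraction, 0)
  expect_lte(sw$inward_fraction, 1)
  # identity cell reproduces the unscaled run
  id <- sw$grid$log_aer == 0 & sw$grid$log_amit == 0 & sw$grid$log_apm == 0
  expect_equal(sum(id), 1)
  tr <- simulate(m, ca_mit = 0.25, t_max = 900)
  o <- detect_oscillation(tr)
  expect_equal(sw$grid$J_mit_to_cyt[id],
               period_average(tr, "J_mit_to_cyt", osc = o),
               tolerance = 1e-10)
})
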