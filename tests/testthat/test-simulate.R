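test_that("identical config and seed reproduce identical tables", {
  cfg <- sim_config(n_patients = 60, seed = 99)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$prescriptions, b2$prescriptions)
  expect_identical(b1$ldl, b2$ldl)
  expect_identical(b1$covariates, b2$covariates)
  expect_identical(b1$truth$latent, b2$truth$latent)
  # a different seed changes the draw
  b3 <- generate_cohort(cfg, seed = 100)
  expect_false(identical(b1$ldl, b3$ldl))
})

test_that("noise-free uncounfounded propagation gives LR_1 = beta * PDC exactly", {
  cfg <- null_confounding_config(25, seed = 5,
                                 beta_direct = c(-0.0035, 0, 0),
                                 carry_coef = 0, pdc_mean = 100,
                                 pdc_noise_sd = 0, lr_noise_sd = 0)
  d <- generate_msm_data(cfg)
  expect_equal(d$pdc_1, rep(100, 25))
  expect_equal(d$lr_1, rep(-0.35, 25))
  expect_equal(d$ldl_1, d$ldl0 * 0.65)
})

test_that("prescription rendering inverts the PDC formula within 2 points", {
  for (pdc in c(10, 25, 50, 75, 100, 140)) {
    for (W in c(200, 365, 420)) {
      rx <- render_prescriptions(pdc, c(0, W), jitter_sd = 0)
      got <- compute_pdc(rx, study_window(0, W))
      expect_lt(abs(got - pdc), 2)
    }
  }
  # hand-enumerated refill schedules are exact
  expect_equal(render_prescriptions(100, c(0, 84), jitter_sd = 0)$date_day,
               c(0, 28, 56))
  expect_equal(render_prescriptions(50, c(0, 112), jitter_sd = 0)$date_day,
               c(0, 56))
  rx70 <- render_prescriptions(70, c(0, 80), jitter_sd = 0)
  expect_equal(rx70$date_day, c(0, 40))
  expect_equal(compute_pdc(rx70, study_window(0, 80)), 70)
  # degenerate inputs
  expect_equal(nrow(render_prescriptions(0, c(0, 100))), 0L)
  expect_error(render_prescriptions(151, c(0, 100)), "\\[0, 150\\]")
})

test_that("visit timing is calibrated to ~3 years to the third measure", {
  d <- generate_msm_data(sim_config(n_patients = 1000, seed = 77))
  yrs <- mean(d$visit_day_3) / 365.25
  expect_gt(yrs, 2.5)
  expect_lt(yrs, 3.5)
})

test_that("adherence feedback induces real time-varying confounding", {
  d <- generate_msm_data(sim_config(n_patients = 5000, seed = 78))
  expect_gt(abs(cor(d$pdc_2, d$lr_1)), 0.1)
})

test_that("latent interval PDCs stay in [0, 150] and dates are ordered", {
  b <- generate_cohort(sim_config(n_patients = 80, seed = 12))
  lat <- b$truth$latent
  for (k in 1:3) {
    expect_true(all(lat[[paste0("pdc_", k)]] >= 0))
    expect_true(all(lat[[paste0("pdc_", k)]] <= 150))
  }
  expect_true(all(b$prescriptions$patient_id %in% b$covariates$patient_id))
  expect_true(all(b$ldl$patient_id %in% b$covariates$patient_id))
  by_id <- split(b$prescriptions$date_day, b$prescriptions$patient_id)
  expect_true(all(vapply(by_id, function(x) all(diff(x) >= 0), logical(1))))
})

test_that("planted violations are recorded in a ledger and land in the tables", {
  b <- generate_cohort(sim_config(n_patients = 40, seed = 13))
  p <- plant_violations(b, list(pdc_gt_200 = 5, ldl_low = 3))
  expect_equal(as.vector(table(p$violations$violation)[c("ldl_low", "pdc_gt_200")]),
               c(3L, 5L))
  expect_equal(sum(p$ldl$ldl_mmol_l == 0.5), 3L)

  # empty plan: identity
  p0 <- plant_violations(b, list())
  expect_identical(p0$prescriptions, b$prescriptions)
  expect_identical(p0$ldl, b$ldl)
  expect_equal(nrow(p0$violations), 0L)

  expect_error(plant_violations(b, list(ldl_low = 100)), "exceed")
})

test_that("cohort tables survive a CSV round trip", {
  b <- generate_cohort(sim_config(n_patients = 15, seed = 3))
  dir <- tempfile("cohort")
  write_cohort(b, dir)
  expect_setequal(list.files(dir), c("prescriptions.csv", "ldl.csv",
                                     "covariates.csv", "events.csv",
                                     "truth.json"))
  b2 <- read_cohort(dir)
  expect_equal(b2$prescriptions$date_day, b$prescriptions$date_day)
  expect_equal(b2$ldl$ldl_mmol_l, b$ldl$ldl_mmol_l, tolerance = 1e-12)
  expect_equal(b2$covariates$age, b$covariates$age, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(K = 0), "K")
  expect_error(sim_config(pdc_noise_sd = -1), "deviations")
  expect_error(sim_config(tablets_per_script = 0), "tablets_per_script")
})
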