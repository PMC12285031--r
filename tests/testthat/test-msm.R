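test_that("weights concentrate near 1 when there is nothing to balance", {
  d <- generate_msm_data(null_confounding_config(5000, seed = 21))
  des <- msm_design(d)
  w <- estimate_weights(des)
  # under the null the only spread left is the overfitting floor of the
  # K Gaussian denominator fits, about sqrt(K * p / n) ~= 0.10 here
  expect_lt(sd(w$w), 0.15)
  expect_equal(mean(w$w), 1, tolerance = 1e-9)
  expect_true(all(w$w > 0))
  # confounding inflates the spread well beyond that floor
  d1 <- generate_msm_data(sim_config(n_patients = 5000, seed = 21))
  des1 <- msm_design(d1)
  expect_gt(sd(estimate_weights(des1)$w), 2 * sd(w$w))
})

test_that("a single-patient design gets the degenerate unit weight", {
  d <- generate_msm_data(sim_config(n_patients = 1, seed = 2, K = 1))
  des <- msm_design(d, K = 1)
  w <- estimate_weights(des)
  expect_equal(w$w, 1)
})

test_that("balancing calibration achieves the 0.1 criterion on confounded data", {
  d <- generate_msm_data(sim_config(n_patients = 5000, seed = 22))
  des <- msm_design(d)
  w <- estimate_weights(des)
  expect_equal(w$method, "parametric_cbps")
  bal <- check_balance(w, des)
  non_visit <- !grepl("^visit_day_", bal$summary$covariate)
  expect_true(all(bal$summary$pass[non_visit]))
  # before weighting, the lagged-outcome confounder is visibly imbalanced
  bal0 <- check_balance(rep(1, des$n), des)
  expect_gt(max(abs(bal0$pairs$pearson[bal0$pairs$covariate == "prior_lr"])), 0.1)
})

test_that("weighted correlations reduce to ordinary ones under equal weights", {
  d <- generate_msm_data(sim_config(n_patients = 400, seed = 23))
  des <- msm_design(d)
  bal <- check_balance(rep(1, des$n), des)
  for (k in 1:3) {
    a <- des$A[, k]
    Xk <- des$X[[k]]
    sub <- bal$pairs[bal$pairs$k == k, ]
    expect_equal(sub$pearson, unname(cor(a, Xk)[1, ]), tolerance = 1e-12)
    expect_equal(sub$spearman,
                 unname(cor(rank(a), apply(Xk, 2, rank))[1, ]),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance covariates are reported NA and never pass", {
  n <- 50
  des <- structure(list(
    A = matrix(rnorm(n), n, 1), L = matrix(rnorm(n), n, 1),
    X = list(cbind(flat = rep(1, n), ok = rnorm(n))),
    K = 1L, n = n, fixed_names = c("flat", "ok"),
    visit_names = "visit_day_1", patient_id = seq_len(n)),
    class = "msm_design")
  bal <- check_balance(rep(1, n), des)
  flat <- bal$summary[bal$summary$covariate == "flat", ]
  expect_true(is.na(flat$avg_abs_corr))
  expect_false(flat$pass)
  expect_true("flat" %in% bal$failed_covariates)
})

test_that("equal weights reduce the weighted MSM to ordinary least squares", {
  d <- generate_msm_data(sim_config(n_patients = 800, seed = 24))
  des <- msm_design(d)
  est <- fit_weighted_msm(des, as_weight_set(rep(1, des$n)))
  for (k in 1:3) {
    ref <- coef(lm(d[[paste0("lr_", k)]] ~ as.matrix(d[paste0("pdc_", 1:k)])))
    expect_equal(unname(est$coef[k, 1:k]), unname(ref[-1]), tolerance = 1e-10)
  }
})

test_that("noise-free linear system is recovered to machine precision", {
  # exposure variance comes from confounders and its own noise; the outcome
  # equation is exactly LR_k = beta_k * PDC_k, so OLS is exact
  cfg <- sim_config(n_patients = 200, seed = 25,
                    beta_direct = c(-0.002, -0.002, -0.002), carry_coef = 0,
                    feedback_coef = 0, pdc_noise_sd = 15, lr_noise_sd = 0,
                    conf_coefs = list(pdc = c(age = 0.34, female = 0.64,
                                              ldl0 = 0.55, education = 0.5),
                                      lr = c(age = 0, female = 0, ldl0 = 0,
                                             education = 0)))
  d <- generate_msm_data(cfg)
  des <- msm_design(d)
  est <- fit_weighted_msm(des, as_weight_set(rep(1, des$n)))
  for (k in 1:3) expect_equal(est$coef[k, k], -0.002, tolerance = 1e-12)
})

test_that("weighting removes the feedback-confounding bias that naive OLS shows", {
  cfg <- sim_config(n_patients = 5000, seed = 26)
  tr <- true_msm_coef(cfg)
  R <- 30
  iptw <- naive <- matrix(NA_real_, R, 2) # columns: b_{3,1}, b_{3,3}
  for (r in seq_len(R)) {
    d <- generate_msm_data(cfg, seed = 2600 + r)
    des <- msm_design(d)
    w <- estimate_weights(des)
    e1 <- fit_weighted_msm(des, w)
    e0 <- fit_weighted_msm(des, as_weight_set(rep(1, des$n)))
    iptw[r, ] <- e1$coef[3, c(1, 3)]
    naive[r, ] <- e0$coef[3, c(1, 3)]
  }
  # weighted estimate tracks the truth on the early-adherence pathway
  expect_lt(abs(mean(iptw[, 1]) - tr[3, 1]), 0.5 * sd(iptw[, 1]))
  # naive OLS misses it badly (relative bias above 10%)
  expect_gt(abs(mean(naive[, 1]) - tr[3, 1]) / abs(tr[3, 1]), 0.10)
})

test_that("recency ordering emerges with equal direct effects and carry-over", {
  cfg <- sim_config(n_patients = 5000, seed = 27,
                    beta_direct = c(-0.0012, -0.0012, -0.0012),
                    carry_coef = 0.4)
  d <- generate_msm_data(cfg)
  des <- msm_design(d)
  est <- fit_weighted_msm(des, estimate_weights(des))
  b3 <- est$coef[3, ]
  expect_gt(abs(b3[3]), abs(b3[2]))
  expect_gt(abs(b3[2]), abs(b3[1]))
})

test_that("intervention contrasts obey the linear-model identities", {
  d <- generate_msm_data(sim_config(n_patients = 600, seed = 28))
  des <- msm_design(d)
  est <- fit_weighted_msm(des, estimate_weights(des), n_boot = 20, seed = 1)

  a <- c(100, 100, 100); z <- c(0, 0, 0); m <- c(60, 30, 80)
  expect_identical(intervention_contrast(est, a, a)$contrast, 0)
  expect_equal(intervention_contrast(est, a, z)$contrast,
               100 * sum(est$coef[3, ]))
  expect_equal(intervention_contrast(est, a, m)$contrast +
                 intervention_contrast(est, m, z)$contrast,
               intervention_contrast(est, a, z)$contrast, tolerance = 1e-12)
  ic <- intervention_contrast(est, a, z)
  expect_true(is.finite(ic$ci_lo) && is.finite(ic$ci_hi))
  expect_true(ic$ci_lo < ic$contrast && ic$contrast < ic$ci_hi)
  expect_error(intervention_contrast(est, c(100, 100), z), "length")
})

test_that("personal-maximum contrast evaluates the stated examples", {
  est <- structure(list(coef = rbind(c(-0.001, NA, NA), c(-0.001, -0.002, NA),
                                     c(-0.001, -0.002, -0.001)),
                        K = 3L, boot = NULL, conf_level = 0.95,
                        ci_type = "norm"), class = "msm_estimate")
  r <- personal_max_contrast(est, matrix(c(100, 50, 100), 1))
  expect_equal(r$contrast, -0.1)
  # constant profiles contribute nothing
  r2 <- personal_max_contrast(est, matrix(70, 4, 3))
  expect_equal(r2$contrast, 0)
  expect_equal(r2$per_patient, rep(0, 4))
})

test_that("collinear confounders are rejected with a useful error", {
  d <- generate_msm_data(sim_config(n_patients = 100, seed = 29))
  d$age2 <- d$age
  expect_error(estimate_weights(msm_design(d, fixed = c("age", "age2", "ldl0"))),
               "collinear")
})

test_that("end-to-end assembly from raw tables recovers the latent structure", {
  b <- generate_cohort(sim_config(n_patients = 400, seed = 30))
  dat <- assemble_msm_data(b)
  expect_gt(nrow(dat), 380)
  m <- merge(dat, b$truth$latent[, c("patient_id", paste0("pdc_", 1:3))],
             by = "patient_id", suffixes = c("", ".true"))
  for (k in 1:3) {
    expect_lt(max(abs(m[[paste0("pdc_", k)]] - m[[paste0("pdc_", k, ".true")]])),
              2)
  }
  des <- msm_design(dat)
  est <- fit_weighted_msm(des, estimate_weights(des))
  # same order of magnitude as the generating direct effects at this n
  expect_lt(abs(est$coef[1, 1] - b$truth$msm_coef[1, 1]), 6e-4)
})
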