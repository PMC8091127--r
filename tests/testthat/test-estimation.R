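truth <- truth_params()

test_that("variance_params validates and prints", {
  expect_error(variance_params(-0.1, 1), class = "ser_validation_error")
  expect_error(variance_params(0.1, -1), class = "ser_validation_error")
  expect_error(variance_params(NA, 1), class = "ser_validation_error")
  v <- variance_params(0, 0)  # noise-free simulation scenarios are legal
  expect_s3_class(v, "variance_params")
})

test_that("subject_nll equals the joint Gaussian negative log density", {
  sub <- list(base = 12, auc = 1500, days = c(1, 3, 7),
              dv = c(10.5, 8.2, 6.9))
  v <- variance_params(0.08, 1.96)
  eta <- 0.03
  pred <- predict_sofa(sub$days, sub$base, sub$auc, truth$params, eta)
  manual <- -sum(dnorm(sub$dv, pred, v$sigma, log = TRUE)) -
    dnorm(eta, 0, v$omega, log = TRUE)
  expect_equal(subject_nll(sub, truth$params, v, eta), manual)
  # single observation exactly at the prediction, sigma = 1, omega = 0:
  # nll = 0.5 log(2 pi)
  sub1 <- list(base = 10, auc = 0, days = 2,
               dv = predict_sofa(2, 10, 0, truth$params))
  expect_equal(subject_nll(sub1, truth$params, variance_params(0, 1)),
               0.5 * log(2 * pi))
  expect_error(subject_nll(sub, truth$params, variance_params(0.1, 0)),
               class = "ser_validation_error")
})

test_that("omega = 0 OFV equals the closed-form Gaussian -2LL (<= 1e-10)", {
  ds <- small_mixed_dataset()
  v0 <- variance_params(0, 1.96)
  manual <- 0
  for (id in ds$subjects$id) {
    sub <- get_subject(ds, id)
    keep <- sub$days > 0
    pred <- predict_sofa(sub$days[keep], sub$base, sub$auc, truth$params)
    manual <- manual - 2 * sum(dnorm(sub$dv[keep], pred, 1.96, log = TRUE))
  }
  for (m in c("foce", "laplace", "agq"))
    expect_equal(marginal_ofv(ds, truth$params, v0, method = m), manual,
                 tolerance = 1e-10)
})

test_that("AGQ matches brute-force quadrature on a 5-subject fixture (<= 1e-6)", {
  ds <- small_mixed_dataset()
  agq <- marginal_ofv(ds, truth$params, truth$variance, method = "agq")
  brute <- brute_force_ofv(ds, truth$params, truth$variance)
  expect_lt(abs(agq - brute), 1e-6)
})

test_that("FOCE and Laplace stay close to the AGQ reference", {
  ds <- generate_trial(trial_design(), truth, seed = 5)
  agq <- marginal_ofv(ds, truth$params, truth$variance, method = "agq")
  foce <- marginal_ofv(ds, truth$params, truth$variance, method = "foce")
  lap <- marginal_ofv(ds, truth$params, truth$variance, method = "laplace")
  expect_lt(abs(foce - agq), 2)
  expect_lt(abs(lap - agq), 2)
  expect_error(marginal_ofv(ds, truth$params, truth$variance,
                            method = "agq", n_nodes = 10),
               class = "ser_validation_error")
})

test_that("fitting is deterministic under a fixed seed and config", {
  ds <- generate_trial(trial_design(), truth, seed = 3)
  cfg <- list(seed = 7, starts = 2, se = FALSE)
  f1 <- fit_er_model(ds, init = table1_init(), config = cfg)
  f2 <- fit_er_model(ds, init = table1_init(), config = cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$ofv, f2$ofv)
})

test_that("unknown config keys and degenerate datasets are rejected", {
  ds <- generate_trial(trial_design(), truth, seed = 3)
  expect_error(fit_er_model(ds, config = list(bogus = 1)),
               class = "ser_validation_error")
  ds_p <- generate_trial(trial_design(arms = arms_with_n(c(6, 1, 1, 1))),
                         truth, seed = 3)
  ds_p$subjects <- ds_p$subjects[ds_p$subjects$arm == "placebo", ]
  ds_only <- trial_dataset(ds_p$subjects,
                           ds_p$observations[ds_p$observations$id %in%
                                               ds_p$subjects$id, ])
  expect_error(fit_er_model(ds_only), class = "ser_validation_error")
})

test_that("fitting data generated with omega = 0 collapses the IIV estimate", {
  tp0 <- truth_params()
  tp0$variance <- variance_params(0, 1.96)
  ds0 <- generate_trial(trial_design(arms = arms_with_n(c(60, 40, 50, 50))),
                        tp0, seed = 7)
  f0 <- fit_er_model(ds0, init = table1_init(),
                     config = list(seed = 1, starts = 2, se = FALSE))
  expect_true(f0$converged)
  expect_lt(f0$variance$omega, 1e-3)
  expect_equal(f0$variance$sigma, 1.96, tolerance = 0.05)
})

test_that("the fitted OFV is never worse than the generating parameters'", {
  ds <- generate_trial(trial_design(), truth, seed = 8)
  f <- fit_er_model(ds, init = table1_init(),
                    config = list(seed = 1, starts = 3, se = FALSE))
  expect_true(f$converged)
  gen <- marginal_ofv(ds, truth$params, truth$variance, method = "foce")
  expect_lte(f$ofv, gen + 1e-6)
})

test_that("profiling each structural parameter away from the MLE does not improve the OFV", {
  ds <- generate_trial(trial_design(), truth, seed = 8)
  f <- fit_er_model(ds, init = table1_init(),
                    config = list(seed = 1, starts = 3, se = FALSE))
  for (nm in c("f_placebo", "k", "kin", "eauc50")) {
    for (fac in c(0.8, 1.2)) {
      val <- f$params[[nm]] * fac
      if (nm == "f_placebo" && val >= 1) next
      args <- f$params[c("f_placebo", "k", "kin", "eauc50")]
      args[[nm]] <- val
      o <- marginal_ofv(ds, do.call(structural_params, args), f$variance,
                        method = "foce")
      # tolerance matches the optimiser's relative convergence criterion;
      # the (kin, eauc50) direction is nearly flat by design
      expect_gte(o, f$ofv - 0.01)
    }
  }
})

test_that("a 500-subject trial recovers the well-identified parameters", {
  arms <- arms_with_n(c(150, 100, 125, 125))
  ds <- generate_trial(trial_design(arms = arms), truth, seed = 500)
  f <- fit_er_model(ds, init = table1_init(),
                    config = list(seed = 1, starts = 2, se = FALSE))
  expect_true(f$converged)
  expect_equal(f$params$f_placebo, 0.792, tolerance = 0.10)
  expect_equal(f$params$k, 0.263, tolerance = 0.10)
  expect_equal(f$variance$sigma, 1.96, tolerance = 0.10)
  # kin and eauc50 sit on a near-flat likelihood ridge (only their ratio is
  # well determined at these estimates): looser single-trial check
  expect_equal(f$params$kin, 0.0569, tolerance = 0.5)
  expect_equal(f$params$eauc50, 1320, tolerance = 0.5)
})

test_that("standard errors are finite and positive when the information matrix cooperates", {
  arms <- arms_with_n(c(30, 20, 25, 25))
  ds <- generate_trial(trial_design(arms = arms), truth, seed = 21)
  f <- fit_er_model(ds, init = table1_init(),
                    config = list(seed = 1, starts = 1))
  expect_true(f$converged)
  expect_true(all(is.finite(f$se[c("f_placebo", "k", "sigma")])))
  expect_true(all(f$se[c("f_placebo", "k", "sigma")] > 0))
  tab <- parameter_table(f)
  expect_named(tab, c("PARAM", "ESTIMATE", "UNITS", "SE", "RSE_PCT",
                      "SHRINK_PCT"))
  expect_identical(tab$PARAM,
                   c("f_placebo", "k", "kin", "eauc50", "omega", "sigma"))
})

test_that("eta shrinkage is low for rich data and near 100% for uninformative data", {
  arms <- arms_with_n(c(20, 10, 10, 10))
  rich <- generate_trial(trial_design(arms = arms, days = seq(0, 8, 0.16)),
                         truth_params(sigma = 0.3), seed = 12)
  f_rich <- fit_at(truth$params, variance_params(truth$variance$omega, 0.3),
                   rich)
  expect_lt(ebes_and_shrinkage(f_rich, rich)$eta_shrinkage_pct, 25)
  noisy <- generate_trial(trial_design(), truth_params(sigma = 200),
                          seed = 13)
  f_noisy <- fit_at(truth$params, variance_params(truth$variance$omega, 200),
                    noisy)
  expect_gt(ebes_and_shrinkage(f_noisy, noisy)$eta_shrinkage_pct, 90)
})
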