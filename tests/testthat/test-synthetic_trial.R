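truth <- truth_params()

test_that("the default design reproduces the published study dimensions", {
  ds <- generate_trial(trial_design(), truth, seed = 1)
  expect_identical(n_subjects(ds), 34L)
  expect_identical(n_observations(ds), 34L * 9L)  # 306 possible scores
  tab <- table(ds$subjects$arm)
  expect_identical(as.integer(tab[c("placebo", "0.06", "0.12", "0.24")]),
                   c(10L, 6L, 9L, 9L))
})

test_that("baselines are integers in [3, 24]; exposure respects the arm", {
  ds <- generate_trial(trial_design(), truth, seed = 2)
  expect_true(all(ds$subjects$base == round(ds$subjects$base)))
  expect_true(all(ds$subjects$base >= 3 & ds$subjects$base <= 24))
  plc <- ds$subjects$arm == "placebo"
  expect_true(all(ds$subjects$auc[plc] == 0))
  expect_true(all(ds$subjects$auc[!plc] > 0))
  # day-0 observation is the baseline, exactly
  d0 <- ds$observations[ds$observations$day == 0, ]
  expect_equal(d0$dv, ds$subjects$base[match(d0$id, ds$subjects$id)])
})

test_that("omega = sigma = 0 puts every observation on the deterministic curve", {
  tp0 <- truth_params()
  tp0$variance <- variance_params(0, 0)
  ds <- generate_trial(trial_design(), tp0, seed = 3)
  for (id in ds$subjects$id[c(1, 12, 30)]) {
    sub <- get_subject(ds, id)
    expect_equal(sub$dv, predict_sofa(sub$days, sub$base, sub$auc,
                                      truth$params))
  }
})

test_that("identical seeds give bit-identical datasets", {
  d1 <- generate_trial(trial_design(), truth, seed = 77)
  d2 <- generate_trial(trial_design(), truth, seed = 77)
  expect_identical(d1, d2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d1, p1); write_dataset(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("baseline calibration removes the truncation-plus-rounding bias", {
  # realised mean of round(truncnorm(mu, sd)) at the calibrated mu must hit
  # the target to well under the 0.05 re-centring threshold
  for (tgt in list(c(12.10, 4.36), c(9.25, 2.22), c(10.09, 3.86))) {
    mu <- sofaer:::calibrate_baseline_mu(tgt[1], tgt[2])
    set.seed(1)
    draws <- sofaer:::draw_baseline(2e5, tgt[1], tgt[2])
    expect_lt(abs(mean(draws) - tgt[1]), 0.02)
  }
  expect_error(sofaer:::calibrate_baseline_mu(30, 4),
               class = "ser_validation_error")
})

test_that("10,000 placebo baselines match the published mean within 2 SE", {
  arms <- trial_design()$arms[1, ]
  arms$n <- 10000L
  ds <- generate_trial(trial_design(arms = arms, days = 0), truth, seed = 60)
  m <- mean(ds$subjects$base)
  se <- sd(ds$subjects$base) / sqrt(10000)
  expect_lt(abs(m - 12.10), 2 * se)
})

test_that("the dropout hazard truncates follow-up but never the baseline", {
  des <- trial_design(dropout_hazard = 0.055)
  ds <- generate_trial(des, truth, seed = 4)
  expect_lt(n_observations(ds), 306L)
  # every subject keeps day 0, and observed days are a prefix of 0..8
  for (id in ds$subjects$id) {
    days <- get_subject(ds, id)$days
    expect_identical(days, 0:max(days))
  }
  expect_error(trial_design(dropout_hazard = 1),
               class = "ser_validation_error")
})

test_that("analytic clearance calibration matches dose/AUC exactly", {
  des <- trial_design()
  dose_ng <- 0.24 * 70 * 1e6
  cl <- calibrate_clearance(1482.51, dose_ng, log(2) / 2, des, "analytic")
  expect_equal(dose_ng / cl, 1482.51)
  expect_error(calibrate_clearance(-1, dose_ng, 0.3, des),
               class = "ser_validation_error")
})

test_that("default calibration makes the typical measured exposure hit the target", {
  des <- trial_design()
  arms0 <- des$arms; arms0$auc_sd <- 0  # noise-free limit
  des0 <- trial_design(arms = arms0)
  profs <- generate_pk_profiles(des0, seed = 1, n_per_arm = 1)
  summ <- suppressMessages(exposure_from_profiles(profs))
  target <- des$arms$auc_mean[match(sub("-.*", "", summ$ID),
                                    des$arms$label)]
  expect_equal(summ$AUC_USED, target, tolerance = 1e-10)
})

test_that("PK profiles cover both occasions at the protocol times", {
  des <- trial_design()
  profs <- generate_pk_profiles(des, seed = 5)
  expect_length(profs, 2L * 24L)  # two occasions per drug subject
  occ <- vapply(profs, `[[`, "", "occasion")
  first <- profs[[which(occ == "first_dose")[1]]]
  last <- profs[[which(occ == "last_dose")[1]]]
  expect_equal(first$time, des$pk_first)
  expect_equal(last$time, des$pk_last)
  # accumulation: last-dose trough exceeds the first-dose value at 6 h is
  # not guaranteed, but concentrations are non-negative everywhere
  expect_true(all(vapply(profs, function(p) all(p$conc >= 0), logical(1))))
})

test_that("profile CSV writer round-trips through the NCA reader", {
  des <- trial_design()
  profs <- generate_pk_profiles(des, seed = 6, n_per_arm = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_conc_profiles(profs, path)
  back <- read_conc_profiles(path)
  expect_length(back, length(profs))
  s1 <- suppressMessages(exposure_from_profiles(profs))
  s2 <- suppressMessages(exposure_from_profiles(back))
  s2 <- s2[match(s1$ID, s2$ID), ]
  expect_equal(s1$AUC_USED, s2$AUC_USED, tolerance = 1e-6)
})
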