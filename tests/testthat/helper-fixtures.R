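# Shared fixtures for the test suite.

# Final-model estimates used both as simulation truth and as natural-scale
# starting values for refits.
table1_init <- function() {
  list(f_placebo = 0.792, k = 0.263, kin = 0.0569, eauc50 = 1320,
       omega = 0.302 * 0.263, sigma = 1.96)
}

# Default arm table with the per-arm n replaced (keeps the published
# baseline/AUC summaries).
arms_with_n <- function(n) {
  tp <- trial_design()
  arms <- tp$arms
  stopifnot(length(n) == nrow(arms))
  arms$n <- as.integer(n)
  arms
}

# Tiny mixed fixture used by the quadrature oracle tests: 2 placebo + 3
# drug subjects (one per dose arm).
small_mixed_dataset <- function(seed = 11) {
  generate_trial(trial_design(arms = arms_with_n(c(2, 1, 1, 1))),
                 truth_params(), seed = seed)
}

# Brute-force marginal -2LL by dense trapezoidal quadrature over eta,
# independent of the package's Laplace/AGQ machinery.
brute_force_ofv <- function(dataset, params, variance,
                            half_width = 8, n_grid = 4001L) {
  eta_grid <- seq(-half_width * variance$omega, half_width * variance$omega,
                  length.out = n_grid)
  total <- 0
  for (id in dataset$subjects$id) {
    sub <- get_subject(dataset, id)
    keep <- sub$days > 0
    sub$days <- sub$days[keep]; sub$dv <- sub$dv[keep]
    log_f <- vapply(eta_grid, function(e)
      -subject_nll(sub, params, variance, e), numeric(1))
    m <- max(log_f)
    integral <- pracma::trapz(eta_grid, exp(log_f - m))
    total <- total - 2 * (m + log(integral))
  }
  total
}

# A fit-shaped object at known parameters (for diagnostics at truth
# without running the estimator).
fit_at <- function(params, variance, dataset) {
  fit <- structure(list(params = params, variance = variance,
                        include_day0 = FALSE, method = "foce"),
                   class = "er_fit")
  eb <- ebes_and_shrinkage(fit, dataset)
  fit$ebes <- eb$ebes
  fit
}
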