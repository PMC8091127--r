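#' Random-effect and residual variability parameters
#'
#' The model carries a single subject-level random effect, an additive
#' normal deviation `eta_k` on the standard-of-care rate constant
#' (`omega` = SD, 1/day), and an additive normal residual on SOFA
#' (`sigma` = SD, SOFA units).  Inter-individual variability on `kin` and
#' `eauc50` is fixed to zero.
#'
#' @param omega SD of `eta_k`, 1/day, `>= 0`.
#' @param sigma residual SD, SOFA units, `>= 0` (must be strictly positive
#'   for likelihood evaluation; `sigma = 0` is accepted for noise-free
#'   simulation scenarios only).
#' @return An object of class `variance_params`.
#' @export
variance_params <- function(omega, sigma) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega < 0)
    stop_validation("omega must be a single finite number >= 0")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop_validation("sigma must be a single finite number >= 0")
  structure(list(omega = omega, sigma = sigma), class = "variance_params")
}

#' @export
print.variance_params <- function(x, ...) {
  cat(sprintf("Variability: omega (SD of eta_k) = %.4g /day, sigma = %.4g SOFA units\n",
              x$omega, x$sigma))
  invisible(x)
}

# Group sums over subjects.  Observations are sorted by subject index; in
# the balanced case a matrix column sum is used, otherwise a cumulative-sum
# trick that handles empty subjects.
make_grpsum <- function(nobs) {
  n <- length(nobs)
  if (n > 0L && nobs[1L] > 0L && all(nobs == nobs[1L])) {
    m <- nobs[1L]
    return(function(x) .colSums(x, m, n))
  }
  ends1 <- cumsum(nobs) + 1L
  function(x) {
    padded <- c(0, cumsum(x))
    diff(c(0, padded[ends1]))
  }
}

#' Joint negative log density of one subject's data and random effect
#'
#' \deqn{\sum_i \left[\tfrac12\log(2\pi\sigma^2) +
#'   (y_i - f_i(\eta))^2 / (2\sigma^2)\right] +
#'   \tfrac12\log(2\pi\omega^2) + \eta^2/(2\omega^2)}
#'
#' For `omega = 0` the prior term is omitted and `eta` is forced to zero
#' (the random effect is degenerate at its mode).
#'
#' @param subject a subject record as returned by [get_subject()] (a list
#'   with `base`, `auc`, `days`, `dv`).
#' @param params [structural_params()].
#' @param variance [variance_params()].
#' @param eta value of the subject random effect, 1/day.
#' @return the joint negative log density (a single number).
#' @export
subject_nll <- function(subject, params, variance, eta = 0) {
  stopifnot(inherits(params, "structural_params"),
            inherits(variance, "variance_params"))
  if (variance$sigma <= 0)
    stop_validation("sigma must be > 0 for likelihood evaluation")
  if (variance$omega == 0) eta <- 0
  p <- predict_sofa(subject$days, subject$base, subject$auc, params, eta)
  r <- subject$dv - p
  s2 <- variance$sigma^2
  out <- sum(0.5 * log(2 * pi * s2) + r^2 / (2 * s2))
  if (variance$omega > 0) {
    w2 <- variance$omega^2
    out <- out + 0.5 * log(2 * pi * w2) + eta^2 / (2 * w2)
  }
  out
}

# Vectorised inner problem: posterior modes of eta for all subjects at once.
# Returns the mode, the joint nll at the mode, and the Gauss-Newton and full
# Hessians of the joint nll with respect to eta.
inner_modes <- function(flat, params, variance, max_iter = 60L, tol = 1e-10) {
  fp <- params$f_placebo; k <- params$k
  s2 <- variance$sigma^2; w2 <- variance$omega^2
  R <- latent_response(flat$t, flat$auc, params)
  drug <- (1 - fp) * flat$base * (1 - R)
  gs <- make_grpsum(flat$nobs)
  const <- flat$nobs * 0.5 * log(2 * pi * s2) + 0.5 * log(2 * pi * w2)
  lim <- 10 * variance$omega + 5  # keeps exp(-(k+eta)t) finite
  nll_of <- function(eta) {
    e <- exp(-(k + eta[flat$idx]) * flat$t)
    r <- flat$y - (flat$base - fp * flat$base * (1 - e) - drug)
    gs(r * r) / (2 * s2) + const + eta^2 / (2 * w2)
  }
  eta <- numeric(flat$n_sub)
  nll <- nll_of(eta)
  for (it in seq_len(max_iter)) {
    e <- exp(-(k + eta[flat$idx]) * flat$t)
    pred <- flat$base - fp * flat$base * (1 - e) - drug
    r <- flat$y - pred
    dp <- -fp * flat$base * flat$t * e
    g <- -gs(r * dp) / s2 + eta / w2
    h <- gs(dp * dp) / s2 + 1 / w2
    step <- g / h
    lambda <- rep(1, flat$n_sub)
    for (half in 1:30) {
      eta_new <- eta - lambda * step
      if (any(abs(eta_new) > lim)) eta_new <- pmin(pmax(eta_new, -lim), lim)
      nll_new <- nll_of(eta_new)
      worse <- nll_new > nll + 1e-12
      if (!any(worse)) break
      lambda[worse] <- lambda[worse] / 2
    }
    moved <- max(abs(eta_new - eta))
    better <- nll_new <= nll + 1e-12
    eta[better] <- eta_new[better]
    nll[better] <- nll_new[better]
    if (moved < tol) break
  }
  e <- exp(-(k + eta[flat$idx]) * flat$t)
  pred <- flat$base - fp * flat$base * (1 - e) - drug
  r <- flat$y - pred
  dp <- -fp * flat$base * flat$t * e
  d2p <- fp * flat$base * flat$t^2 * e
  h_gn <- gs(dp * dp) / s2 + 1 / w2
  h_full <- h_gn - gs(r * d2p) / s2
  list(eta = eta, nll = nll, h_gn = h_gn, h_full = h_full)
}

# -2 log-likelihood with no random effect (omega = 0): closed-form additive
# Gaussian contribution at eta = 0, no prior or Laplace terms.
ofv_no_raneff <- function(flat, params, variance) {
  p <- predict_sofa(flat$t, flat$base, flat$auc, params, 0)
  r <- flat$y - p
  s2 <- variance$sigma^2
  sum(log(2 * pi * s2) + r^2 / s2)
}

#' Marginal objective function value (-2 log likelihood)
#'
#' Integrates the single subject-level random effect out of the joint
#' likelihood, subject by subject, and returns
#' \eqn{-2 \sum_s \log \int e^{-\mathrm{nll}_s(\eta)} d\eta}.
#'
#' Methods:
#' * `"foce"` -- Laplace approximation at the posterior mode using the
#'   Gauss-Newton (first-order) Hessian; with a purely additive residual
#'   this coincides with FOCE-with-interaction.
#' * `"laplace"` -- same with the full second-order Hessian.
#' * `"agq"` -- adaptive Gauss-Hermite quadrature centred and scaled at the
#'   mode; the reference method bounding the FOCE approximation error.
#'
#' Placebo subjects carry the random effect too (their standard-of-care
#' rate varies between subjects).  For `omega = 0` the closed-form additive
#' Gaussian -2 log likelihood at `eta = 0` is returned.
#'
#' @param dataset a [trial_dataset()].
#' @param params [structural_params()].
#' @param variance [variance_params()].
#' @param method `"foce"`, `"agq"` or `"laplace"`.
#' @param n_nodes odd number of quadrature nodes for `"agq"`.
#' @param include_day0 include day-0 (pre-dose) rows in the likelihood.
#'   Off by default: the day-0 value reproduces the baseline covariate
#'   exactly and would understate `sigma`.
#' @return The OFV (a single number).
#' @export
marginal_ofv <- function(dataset, params, variance,
                         method = c("foce", "agq", "laplace"), n_nodes = 31L,
                         include_day0 = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "trial_dataset"))
  flat <- flatten_dataset(dataset, include_day0)
  ofv_flat(flat, params, variance, method, n_nodes)
}

ofv_flat <- function(flat, params, variance, method = "foce", n_nodes = 31L) {
  if (variance$sigma <= 0)
    stop_validation("sigma must be > 0 for likelihood evaluation")
  if (variance$omega < 1e-8)
    return(ofv_no_raneff(flat, params, variance))
  im <- inner_modes(flat, params, variance)
  if (any(!is.finite(im$nll)))
    stop_numerical("inner mode search failed for subject(s): %s",
                   paste(flat$ids[!is.finite(im$nll)], collapse = ", "))
  if (method == "foce")
    return(sum(2 * im$nll - log(2 * pi) + log(im$h_gn)))
  if (method == "laplace") {
    h <- ifelse(im$h_full > 0, im$h_full, im$h_gn)
    return(sum(2 * im$nll - log(2 * pi) + log(h)))
  }
  # agq
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L || n_nodes %% 2L == 0L)
    stop_validation("n_nodes must be odd and >= 1 for agq")
  gh <- pracma::gaussHermite(n_nodes)
  h <- ifelse(im$h_full > 0, im$h_full, im$h_gn)
  sL <- 1 / sqrt(h)
  fp <- params$f_placebo; k <- params$k
  s2 <- variance$sigma^2; w2 <- variance$omega^2
  R <- latent_response(flat$t, flat$auc, params)
  drug <- (1 - fp) * flat$base * (1 - R)
  gs <- make_grpsum(flat$nobs)
  const <- flat$nobs * 0.5 * log(2 * pi * s2) + 0.5 * log(2 * pi * w2)
  M <- matrix(NA_real_, flat$n_sub, n_nodes)
  for (j in seq_len(n_nodes)) {
    eta_j <- im$eta + sL * gh$x[j]
    e <- exp(-(k + eta_j[flat$idx]) * flat$t)
    r <- flat$y - (flat$base - fp * flat$base * (1 - e) - drug)
    nll_j <- gs(r * r) / (2 * s2) + const + eta_j^2 / (2 * w2)
    M[, j] <- log(gh$w[j]) + gh$x[j]^2 - nll_j
  }
  logI <- log(sL) + apply(M, 1L, logsumexp)
  -2 * sum(logI)
}

# parameter transform: unconstrained theta <-> natural scale
theta_from <- function(params, variance) {
  c(qlogis(params$f_placebo), log(params$k), log(params$kin),
    log(params$eauc50), log(variance$omega), log(variance$sigma))
}

theta_to <- function(theta) {
  list(params = structural_params(plogis(theta[1L]), exp(theta[2L]),
                                  exp(theta[3L]), exp(theta[4L])),
       variance = variance_params(exp(theta[5L]), exp(theta[6L])))
}

theta_names <- c("f_placebo", "k", "kin", "eauc50", "omega", "sigma")

default_fit_config <- function() {
  list(method = "foce", n_nodes = 31L, starts = 5L, seed = NULL,
       jitter_sd = 0.3, include_day0 = FALSE, maxit = 500L, factr = 4.5e7,
       se = TRUE, bounds = NULL)
}

#' Fit the exposure-response model by nonlinear mixed-effects estimation
#'
#' Maximises the marginal likelihood over the transformed parameter vector
#' (logit `f_placebo`; log `k`, `kin`, `eauc50`, `omega`, `sigma`) with
#' L-BFGS-B and multi-start jitter.  `kin = kout` is tied structurally and
#' inter-individual variability acts on `k` only.  The observed baseline is
#' a covariate, never estimated.
#'
#' Default bounds keep the optimum physiologically interpretable: rates in
#' `[1e-3, 10]`/day (`kin` down to 1e-4), `eauc50` within 10 times the
#' largest observed exposure (beyond which the half-maximal exposure is not
#' identifiable from the data by construction), `omega` in `[1e-6, 10]`,
#' `sigma` in `[1e-3, 100]`.
#'
#' @param dataset a [trial_dataset()] with at least one non-placebo subject.
#' @param init optional named list/vector of natural-scale starting values
#'   (`f_placebo`, `k`, `kin`, `eauc50`, `omega`, `sigma`).
#' @param config list of options overriding the defaults: `method`
#'   (`"foce"`/`"agq"`/`"laplace"`), `n_nodes`, `starts`, `seed`,
#'   `jitter_sd` (transformed scale), `include_day0`, `maxit`, `factr`
#'   (L-BFGS-B tolerance), `se` (compute standard errors), `bounds`
#'   (named list of `c(lower, upper)` on the natural scale).
#' @return An object of class `er_fit`: estimates, `ofv`, standard errors
#'   and RSE%, empirical Bayes estimates, shrinkages, convergence flag and
#'   evaluation count.
#' @export
fit_er_model <- function(dataset, init = NULL, config = list()) {
  stopifnot(inherits(dataset, "trial_dataset"))
  cfg <- default_fit_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop_validation("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config

  if (all(dataset$subjects$auc == 0))
    stop_validation(paste("all subjects are placebo: eauc50 and kin are not",
                          "identifiable; fix the drug parameters or supply",
                          "drug-arm data"))
  flat <- flatten_dataset(dataset, cfg$include_day0)
  if (length(flat$y) == 0L)
    stop_validation("no post-baseline observations to fit")

  ini <- list(f_placebo = 0.5, k = 0.1, kin = 0.1,
              eauc50 = median(dataset$subjects$auc[dataset$subjects$auc > 0]),
              omega = 0.1, sigma = 2)
  if (!is.null(init)) ini[names(init)] <- init
  theta0 <- theta_from(structural_params(ini$f_placebo, ini$k, ini$kin, ini$eauc50),
                       variance_params(ini$omega, ini$sigma))

  bounds <- list(f_placebo = c(1e-6, 1 - 1e-6), k = c(1e-3, 10),
                 kin = c(1e-4, 10),
                 eauc50 = c(1, 10 * max(dataset$subjects$auc)),
                 omega = c(1e-6, 10), sigma = c(1e-3, 100))
  if (!is.null(cfg$bounds)) bounds[names(cfg$bounds)] <- cfg$bounds
  lower <- c(qlogis(bounds$f_placebo[1L]), log(bounds$k[1L]), log(bounds$kin[1L]),
             log(bounds$eauc50[1L]), log(bounds$omega[1L]), log(bounds$sigma[1L]))
  upper <- c(qlogis(bounds$f_placebo[2L]), log(bounds$k[2L]), log(bounds$kin[2L]),
             log(bounds$eauc50[2L]), log(bounds$omega[2L]), log(bounds$sigma[2L]))
  theta0 <- pmin(pmax(theta0, lower), upper)

  n_eval <- 0L
  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    val <- tryCatch(ofv_flat(flat, theta_to(theta)$params, theta_to(theta)$variance,
                             cfg$method, cfg$n_nodes),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  starts <- list(theta0)
  if (cfg$starts > 1L) {
    for (s in seq_len(cfg$starts - 1L)) {
      jit <- theta0 + rnorm(6L, 0, cfg$jitter_sd)
      starts[[s + 1L]] <- pmin(pmax(jit, lower), upper)
    }
  }
  runs <- lapply(starts, function(th) {
    tryCatch(
      optim(th, objective, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = cfg$maxit, factr = cfg$factr)),
      error = function(e) list(par = th, value = 1e10, convergence = 99L))
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  conv <- vapply(runs, `[[`, numeric(1), "convergence") == 0
  best <- if (any(conv)) which(conv)[which.min(vals[conv])] else which.min(vals)
  opt <- runs[[best]]
  pv <- theta_to(opt$par)

  fit <- structure(list(
    params = pv$params, variance = pv$variance, ofv = opt$value,
    theta = setNames(opt$par, theta_names),
    lower = lower, upper = upper,
    se = setNames(rep(NA_real_, 6L), theta_names),
    rse_pct = setNames(rep(NA_real_, 6L), theta_names),
    ebes = NULL, eta_shrinkage_pct = NA_real_, eps_shrinkage_pct = NA_real_,
    converged = conv[best] && opt$value < 1e10,
    n_function_evals = n_eval, start_ofvs = vals,
    method = cfg$method, include_day0 = cfg$include_day0, config = cfg),
    class = "er_fit")

  eb <- ebes_and_shrinkage(fit, dataset)
  fit$ebes <- eb$ebes
  fit$eta_shrinkage_pct <- eb$eta_shrinkage_pct
  fit$eps_shrinkage_pct <- eb$eps_shrinkage_pct
  if (isTRUE(cfg$se) && fit$converged) {
    se <- standard_errors(fit, dataset)
    fit$se <- se$se
    fit$rse_pct <- se$rse_pct
  }
  fit
}

#' @export
print.er_fit <- function(x, ...) {
  cat(sprintf("Exposure-response model fit (%s)%s\n", x$method,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  OFV: %.4f   function evaluations: %d\n", x$ofv,
              x$n_function_evals))
  print(parameter_table(x), row.names = FALSE)
  invisible(x)
}

#' Tabulate estimates, standard errors and shrinkage
#'
#' @param fit an [fit_er_model()] result.
#' @return data.frame `PARAM, ESTIMATE, UNITS, SE, RSE_PCT, SHRINK_PCT`.
#' @export
parameter_table <- function(fit) {
  est <- c(fit$params$f_placebo, fit$params$k, fit$params$kin,
           fit$params$eauc50, fit$variance$omega, fit$variance$sigma)
  data.frame(
    PARAM = theta_names,
    ESTIMATE = est,
    UNITS = c("", "1/day", "1/day", "h*ng/mL", "1/day", "SOFA"),
    SE = as.numeric(fit$se),
    RSE_PCT = as.numeric(fit$rse_pct),
    SHRINK_PCT = c(NA, fit$eta_shrinkage_pct, NA, NA, NA,
                   fit$eps_shrinkage_pct),
    stringsAsFactors = FALSE)
}

#' Standard errors from the observed information matrix
#'
#' Central finite differences of the marginal -log likelihood on the
#' transformed scale, inverted and delta-method back-transformed to the
#' natural scale.  A non-positive-definite information matrix yields a
#' warning and `NaN` for the affected parameters.
#'
#' @param fit a converged [fit_er_model()] result.
#' @param dataset the dataset the model was fitted to.
#' @return list with named vectors `se` and `rse_pct` (natural scale) and
#'   the transformed-scale covariance matrix `cov`.
#' @export
standard_errors <- function(fit, dataset) {
  stopifnot(inherits(fit, "er_fit"))
  if (!fit$converged)
    stop_numerical("standard errors require a converged fit")
  flat <- flatten_dataset(dataset, fit$include_day0)
  f <- function(theta) 0.5 * ofv_flat(flat, theta_to(theta)$params,
                                      theta_to(theta)$variance,
                                      fit$method, fit$config$n_nodes)
  H <- pracma::hessian(f, as.numeric(fit$theta))
  cov_t <- tryCatch(solve(H), error = function(e) NULL)
  se_t <- rep(NaN, 6L)
  if (is.null(cov_t)) {
    warning("information matrix is singular; standard errors are NaN",
            call. = FALSE)
    cov_t <- matrix(NaN, 6L, 6L)
  } else {
    d <- diag(cov_t)
    if (any(d <= 0))
      warning("information matrix not positive definite; NaN for affected parameters",
              call. = FALSE)
    se_t <- ifelse(d > 0, sqrt(pmax(d, 0)), NaN)
  }
  est <- c(fit$params$f_placebo, fit$params$k, fit$params$kin,
           fit$params$eauc50, fit$variance$omega, fit$variance$sigma)
  jac <- c(est[1L] * (1 - est[1L]), est[2:6])  # d(natural)/d(transformed)
  se <- setNames(se_t * abs(jac), theta_names)
  rse <- setNames(100 * se / abs(est), theta_names)
  list(se = se, rse_pct = rse, cov = cov_t)
}

#' Empirical Bayes estimates and shrinkage
#'
#' Recomputes the per-subject posterior modes of `eta_k` at the supplied
#' fit's estimates.  Eta-shrinkage is `100 (1 - SD(eta_hat)/omega)`;
#' epsilon-shrinkage is `100 (1 - SD(IWRES))` with
#' `IWRES = (DV - IPRED)/sigma`.  Both are `NaN` when `omega = 0`
#' (eta-shrinkage undefined) and negative values are reported with a
#' warning.
#'
#' @inheritParams standard_errors
#' @return list with `ebes` (data.frame `id`, `eta`), `eta_shrinkage_pct`
#'   and `eps_shrinkage_pct`.
#' @export
ebes_and_shrinkage <- function(fit, dataset) {
  stopifnot(inherits(fit, "er_fit"))
  flat <- flatten_dataset(dataset, fit$include_day0)
  if (fit$variance$omega < 1e-8) {
    eta <- numeric(flat$n_sub)
    eta_shr <- NaN
  } else {
    im <- inner_modes(flat, fit$params, fit$variance)
    eta <- im$eta
    eta_shr <- 100 * (1 - sd(eta) / fit$variance$omega)
  }
  ipred <- predict_sofa(flat$t, flat$base, flat$auc, fit$params, eta[flat$idx])
  iwres <- (flat$y - ipred) / fit$variance$sigma
  eps_shr <- if (length(iwres) > 1L) 100 * (1 - sd(iwres)) else NaN
  if (is.finite(eta_shr) && eta_shr < 0)
    warning("negative eta-shrinkage (EBE spread exceeds omega)", call. = FALSE)
  list(ebes = data.frame(id = flat$ids, eta = eta, stringsAsFactors = FALSE),
       eta_shrinkage_pct = eta_shr, eps_shrinkage_pct = eps_shr)
}
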