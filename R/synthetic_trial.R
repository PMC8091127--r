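#' Ground-truth parameters for synthetic trials
#'
#' Defaults are the final model estimates of the Phase-IIa analysis:
#' `f_placebo = 0.792`, `k = 0.263`/day, `kin = kout = 0.0569`/day,
#' `eauc50 = 1320` h*ng/mL, residual SD `sigma = 1.96` SOFA units.  The
#' published inter-individual variability of 30.2 on `k` is read as a CV%
#' by default (`omega = 0.302 * k`); set `iiv_as_cv = FALSE` to read it as
#' the SD itself (0.302/day).
#'
#' @param f_placebo,k,kin,eauc50 structural fixed effects, see
#'   [structural_params()].
#' @param iiv inter-individual variability on `k`: CV fraction when
#'   `iiv_as_cv` is `TRUE`, SD (1/day) otherwise.
#' @param sigma additive residual SD, SOFA units.
#' @param iiv_as_cv interpret `iiv` as a coefficient of variation.
#' @return list with elements `params` ([structural_params()]) and
#'   `variance` ([variance_params()]).
#' @export
truth_params <- function(f_placebo = 0.792, k = 0.263, kin = 0.0569,
                         eauc50 = 1320, iiv = 0.302, sigma = 1.96,
                         iiv_as_cv = TRUE) {
  omega <- if (iiv_as_cv) iiv * k else iiv
  list(params = structural_params(f_placebo, k, kin, eauc50),
       variance = variance_params(omega, sigma))
}

default_arms <- function() {
  data.frame(
    label = c("placebo", "0.06", "0.12", "0.24"),
    n = c(10L, 6L, 9L, 9L),
    base_mean = c(12.10, 9.25, 9.56, 10.09),
    base_sd = c(4.36, 2.22, 3.09, 3.86),
    auc_mean = c(0, 295.21, 827.85, 1482.51),
    auc_sd = c(0, 47.16, 334.10, 378.34),
    dose_mg_kg = c(0, 0.06, 0.12, 0.24),
    stringsAsFactors = FALSE)
}

#' Phase-IIa-like trial design
#'
#' The default emulates the analysed Phase-IIa population: 10 placebo
#' subjects plus 24 drug subjects split 6/9/9 over the 0.06, 0.12 and
#' 0.24 mg/kg q8h arms (only the total of 24 is published; the 6/9/9 split
#' reflects the 6 pre-trial 0.06 mg/kg subjects and is configurable), with
#' the published per-arm baseline-SOFA and AUC(0-8h) means and SDs.  SOFA
#' is observed pre-dose (day 0) and daily for 8 days.  PK sampling follows
#' the protocol: 0, 0.5, 1, 2, 6, 8 h after the first dose and 0, 0.5, 1,
#' 2, 6, 12 h after the last of the 21 q8h one-hour infusions.
#'
#' @param arms data.frame with columns `label`, `n`, `base_mean`,
#'   `base_sd`, `auc_mean`, `auc_sd`, `dose_mg_kg`.
#' @param days SOFA observation days.
#' @param dropout_hazard per-day probability of dropping out after each
#'   post-baseline day (0 = complete follow-up; ~0.055 reproduces the
#'   published 245 of 306 possible scores on average).
#' @param pk_first,pk_last PK sampling times, hours after the start of the
#'   first / last infusion.
#' @param weight_kg body weight used to convert mg/kg doses.
#' @return list of class `trial_design`.
#' @export
trial_design <- function(arms = default_arms(), days = 0:8,
                         dropout_hazard = 0,
                         pk_first = c(0, 0.5, 1, 2, 6, 8),
                         pk_last = c(0, 0.5, 1, 2, 6, 12),
                         weight_kg = 70) {
  need <- c("label", "n", "base_mean", "base_sd", "auc_mean", "auc_sd",
            "dose_mg_kg")
  if (!all(need %in% names(arms)))
    stop_validation("arms must have columns %s", paste(need, collapse = ", "))
  if (any(arms$n < 1L)) stop_validation("each arm needs n >= 1")
  if (any(arms$base_sd < 0) || any(arms$auc_sd < 0))
    stop_validation("arm SDs must be >= 0")
  if (dropout_hazard < 0 || dropout_hazard >= 1)
    stop_validation("dropout_hazard must lie in [0, 1)")
  structure(list(arms = arms, days = sort(unique(days)),
                 dropout_hazard = dropout_hazard,
                 pk_first = pk_first, pk_last = pk_last,
                 weight_kg = weight_kg),
            class = "trial_design")
}

# mu of the truncated([3,24])-and-rounded normal whose mean equals `target`.
# Rounding maps [j-0.5, j+0.5) to integer j (edges clipped to the range),
# so the realised mean of round(truncnorm) is computed exactly from normal
# CDF bin masses and re-centred by root finding.
calibrate_baseline_mu <- function(target, sd, lo = 3, hi = 24) {
  if (target <= lo || target >= hi)
    stop_validation("baseline mean %g outside the feasible range (%g, %g)",
                    target, lo, hi)
  realised <- function(mu) {
    z <- pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
    if (z < 1e-12) return(NA_real_)
    j <- lo:hi
    a <- pmax(j - 0.5, lo); b <- pmin(j + 0.5, hi)
    p <- (pnorm(b, mu, sd) - pnorm(a, mu, sd)) / z
    sum(j * p)
  }
  uniroot(function(mu) realised(mu) - target,
          lower = target - 3 * sd, upper = target + 3 * sd, tol = 1e-10)$root
}

# draw integer baselines from the bias-corrected truncated normal
draw_baseline <- function(n, mean, sd, lo = 3, hi = 24) {
  if (sd == 0) return(rep(mean, n))
  mu <- calibrate_baseline_mu(mean, sd, lo, hi)
  u <- runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd))
  round(qnorm(u, mu, sd))
}

# moment-matched lognormal draws (mean, sd on the natural scale)
draw_lognormal <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

#' Generate a synthetic SOFA trial dataset
#'
#' Per subject: an integer baseline from the bias-corrected truncated
#' normal of its arm, an AUC from a moment-matched lognormal (0 for
#' placebo), a random effect `eta_k ~ N(0, omega^2)`, a day-0 observation
#' equal to the baseline (the pre-dose score *is* the baseline covariate),
#' and post-baseline observations `predict_sofa(...) + eps` with
#' `eps ~ N(0, sigma^2)`.  A per-day dropout hazard truncates later
#' observations.  Fully reproducible under `seed`.
#'
#' @param design a [trial_design()].
#' @param truth a [truth_params()] list.
#' @param seed RNG seed.
#' @param integer_dv clip post-baseline scores to `[0, 24]` and round
#'   (realism mode; biases sigma recovery and is off by default).
#' @return A [trial_dataset()].
#' @export
generate_trial <- function(design, truth, seed = NULL, integer_dv = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  params <- truth$params; variance <- truth$variance
  subj <- list(); obs <- list(); sid <- 0L
  for (a in seq_len(nrow(design$arms))) {
    arm <- design$arms[a, ]
    base <- draw_baseline(arm$n, arm$base_mean, arm$base_sd)
    auc <- if (arm$label == "placebo") rep(0, arm$n)
           else draw_lognormal(arm$n, arm$auc_mean, arm$auc_sd)
    eta <- rnorm(arm$n, 0, variance$omega)
    for (i in seq_len(arm$n)) {
      sid <- sid + 1L
      id <- sprintf("S%03d", sid)
      days <- design$days
      if (design$dropout_hazard > 0) {
        n_post <- sum(days > 0)
        drop_after <- which(runif(n_post) < design$dropout_hazard)
        if (length(drop_after)) {
          cut <- sort(days[days > 0])[min(drop_after)]
          days <- days[days <= cut]
        }
      }
      dv <- ifelse(days == 0, base[i],
                   predict_sofa(days, base[i], auc[i], params, eta[i]) +
                     rnorm(length(days), 0, variance$sigma))
      if (integer_dv) {
        post <- days > 0
        dv[post] <- round(pmin(pmax(dv[post], 0), 24))
      }
      subj[[sid]] <- data.frame(id = id, arm = arm$label, base = base[i],
                                auc = auc[i], stringsAsFactors = FALSE)
      obs[[sid]] <- data.frame(id = id, day = days, dv = dv,
                               stringsAsFactors = FALSE)
    }
  }
  trial_dataset(do.call(rbind, subj), do.call(rbind, obs))
}

# One-compartment constant-rate-infusion superposition: concentration
# (ng/mL) at `t` hours after the start of the first infusion.
conc_infusion <- function(t, dose_ng, cl, ke, dur = 1, tau = 8,
                          n_doses = 21L) {
  r0 <- dose_ng / dur
  out <- numeric(length(t))
  for (m in seq_len(n_doses)) {
    s <- t - (m - 1) * tau
    during <- s >= 0 & s <= dur
    after <- s > dur
    out[during] <- out[during] + r0 / cl * (1 - exp(-ke * s[during]))
    out[after] <- out[after] +
      r0 / cl * (1 - exp(-ke * dur)) * exp(-ke * (s[after] - dur))
  }
  out
}

#' Calibrated clearance for a target measured exposure
#'
#' `calibration = "analytic"` uses the steady-state identity
#' `AUC(0-8h) = dose/CL` exactly.  `calibration = "nca"` (default) instead
#' chooses CL so that the *measured* exposure of the typical subject --
#' protocol sampling times, linear-trapezoid [auc_0_8()] on the first- and
#' last-dose profiles, averaged by [subject_exposure()] -- equals the
#' target, i.e. it calibrates through the same measurement pipeline that
#' produced the published arm means.  Because concentrations scale as 1/CL
#' the correction is a single exact rescaling.
#'
#' @param target_auc target mean AUC(0-8h), h*ng/mL.
#' @param dose_ng dose per infusion, ng.
#' @param ke elimination rate constant, 1/h.
#' @param design a [trial_design()] (for the sampling times).
#' @param calibration `"nca"` or `"analytic"`.
#' @return clearance, mL/h.
#' @export
calibrate_clearance <- function(target_auc, dose_ng, ke, design,
                                calibration = c("nca", "analytic")) {
  calibration <- match.arg(calibration)
  if (target_auc <= 0 || dose_ng <= 0 || ke <= 0)
    stop_validation("target_auc, dose_ng and ke must all be > 0")
  cl0 <- dose_ng / target_auc
  if (calibration == "analytic") return(cl0)
  last_start <- 20 * 8
  prof <- function(times, offset) {
    concentration_profile("typ", if (offset == 0) "first_dose" else "last_dose",
                          times, conc_infusion(times + offset, dose_ng, cl0, ke))
  }
  measured <- suppressMessages(subject_exposure(
    prof(design$pk_first, 0), prof(design$pk_last, last_start)))$auc_used
  cl0 * measured / target_auc
}

#' Generate synthetic PK concentration profiles
#'
#' For each drug-arm subject, first-dose and last-dose concentration-time
#' profiles at the protocol sampling times are produced from a
#' one-compartment model with 1-h constant-rate infusions every 8 h for
#' 7 days (21 doses).  The typical clearance per arm comes from
#' [calibrate_clearance()]; between-subject variability is introduced by
#' drawing each subject's exposure from the arm's moment-matched lognormal
#' AUC distribution and scaling the profile accordingly (NCA is linear in
#' concentration, so the measured exposures inherit that distribution).
#'
#' The paper's PK itself is out of scope here: this layer only has to
#' exercise the NCA module with realistic shapes, and an elimination
#' half-life of 2 h (`ke = log(2)/2`) is assumed.
#'
#' @param design a [trial_design()].
#' @param ke elimination rate constant, 1/h.
#' @param seed RNG seed.
#' @param n_per_arm optional override of the per-arm subject count (e.g.
#'   for calibration studies).
#' @param calibration passed to [calibrate_clearance()].
#' @return list of [concentration_profile()] objects (two per subject).
#' @export
generate_pk_profiles <- function(design, ke = log(2) / 2, seed = NULL,
                                 n_per_arm = NULL,
                                 calibration = c("nca", "analytic")) {
  stopifnot(inherits(design, "trial_design"))
  calibration <- match.arg(calibration)
  if (ke <= 0) stop_validation("ke must be > 0")
  if (!is.null(seed)) set.seed(seed)
  last_start <- 20 * 8
  out <- list()
  for (a in seq_len(nrow(design$arms))) {
    arm <- design$arms[a, ]
    if (arm$dose_mg_kg == 0) next
    dose_ng <- arm$dose_mg_kg * design$weight_kg * 1e6
    cl <- calibrate_clearance(arm$auc_mean, dose_ng, ke, design, calibration)
    n <- n_per_arm %||% arm$n
    scale <- draw_lognormal(n, arm$auc_mean, arm$auc_sd) / arm$auc_mean
    for (i in seq_len(n)) {
      id <- sprintf("%s-%04d", arm$label, i)
      c_first <- conc_infusion(design$pk_first, dose_ng, cl, ke) * scale[i]
      c_last <- conc_infusion(design$pk_last + last_start, dose_ng, cl, ke) *
        scale[i]
      out[[length(out) + 1L]] <-
        concentration_profile(id, "first_dose", design$pk_first, c_first)
      out[[length(out) + 1L]] <-
        concentration_profile(id, "last_dose", design$pk_last, c_last)
    }
  }
  out
}

#' Write PK profiles in the NCA CSV dialect
#' @param profiles list of [concentration_profile()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_conc_profiles <- function(profiles, path) {
  occ_map <- c(first_dose = "FIRST", last_dose = "LAST")
  rows <- lapply(profiles, function(p)
    data.frame(ID = p$id, OCC = occ_map[[p$occasion]], TIME_H = p$time,
               CONC = p$conc, stringsAsFactors = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
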