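#' Structural parameters of the exposure-response model
#'
#' The structural model predicts the SOFA score of a subject at time `t`
#' (days since the first dose) from the observed baseline score, the
#' subject's steady-state exposure `AUC` (h*ng/mL over one 8-h dosing
#' interval), and five fixed effects:
#'
#' \deqn{SOFA(t) = Base - F_p \cdot Base \cdot (1 - e^{-k t})
#'                 - (1 - F_p) \cdot Base \cdot (1 - R(t))}
#'
#' where \eqn{F_p} (`f_placebo`) is the maximal fraction of baseline SOFA
#' removable by standard care alone, `k` (1/day) the standard-of-care
#' amelioration rate, and the latent drug response \eqn{R(t) \in (0, 1]}
#' follows an inhibitory indirect-response model
#'
#' \deqn{dR/dt = k_{in} (1 - AUC / (AUC + EAUC_{50})) - k_{out} R,
#'       \quad R(0) = 1.}
#'
#' The initial condition \eqn{R(0) = 1} together with the steady baseline
#' forces \eqn{k_{in} = k_{out}}, which this constructor enforces.
#'
#' @param f_placebo maximal standard-care fraction, dimensionless in `[0, 1]`.
#' @param k standard-care amelioration rate constant, 1/day, `> 0`.
#' @param kin zero-order production rate of the latent response, 1/day, `> 0`.
#'   `kout` is tied to `kin`.
#' @param eauc50 steady-state AUC giving half-maximal inhibition of the
#'   latent production rate, h*ng/mL, `> 0`.
#' @return An object of class `structural_params`.
#' @seealso [predict_sofa()], [latent_response()]
#' @export
#' @examples
#' p <- structural_params(f_placebo = 0.792, k = 0.263,
#'                        kin = 0.0569, eauc50 = 1320)
#' predict_sofa(t = 7, base = 10, auc = 1500, params = p)
structural_params <- function(f_placebo, k, kin, eauc50) {
  for (nm in c("f_placebo", "k", "kin", "eauc50")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_validation("'%s' must be a single finite number", nm)
  }
  if (f_placebo < 0 || f_placebo > 1)
    stop_validation("f_placebo must lie in [0, 1], got %g", f_placebo)
  if (k <= 0) stop_validation("k must be > 0, got %g", k)
  if (kin <= 0) stop_validation("kin must be > 0, got %g", kin)
  if (eauc50 <= 0) stop_validation("eauc50 must be > 0, got %g", eauc50)
  structure(list(f_placebo = f_placebo, k = k, kin = kin, kout = kin,
                 eauc50 = eauc50),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Structural exposure-response parameters\n")
  cat(sprintf("  f_placebo : %.4g\n", x$f_placebo))
  cat(sprintf("  k         : %.4g /day\n", x$k))
  cat(sprintf("  kin = kout: %.4g /day\n", x$kin))
  cat(sprintf("  eauc50    : %.4g h*ng/mL\n", x$eauc50))
  invisible(x)
}

#' Latent drug response R(t), closed form
#'
#' Solution of the indirect-response turnover equation with `kin = kout`
#' and `R(0) = 1`:
#' \deqn{R(t) = 1 - I (1 - e^{-k_{out} t}), \quad I = AUC/(AUC + EAUC_{50}).}
#' For `auc = 0` (placebo) the inhibition `I` vanishes and `R(t) = 1`
#' identically; as `t` grows, `R` approaches its steady state `1 - I`.
#'
#' @param t time since first dose, days; vectorised, `>= 0`.
#' @param auc steady-state exposure AUC over one dosing interval, h*ng/mL,
#'   `>= 0`; scalar or same length as `t`.
#' @param params a [structural_params()] object.
#' @return Latent response in `(0, 1]`, same length as `t`.
#' @export
latent_response <- function(t, auc, params) {
  stopifnot(inherits(params, "structural_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop_validation("t must be finite and >= 0")
  if (any(!is.finite(auc)) || any(auc < 0))
    stop_validation("auc must be finite and >= 0")
  inh <- auc / (auc + params$eauc50)
  1 - inh * (1 - exp(-params$kout * t))
}

#' Latent drug response R(t) by numerical ODE integration
#'
#' Integrates the turnover equation with an adaptive-step solver
#' (`deSolve::lsoda`).  Retained as an independent numerical oracle for
#' [latent_response()] and as the natural extension point should `kin` and
#' `kout` ever be decoupled; the closed form is used everywhere in the
#' likelihood for speed.
#'
#' @inheritParams latent_response
#' @param auc scalar exposure for the integrated trajectory.
#' @param tol relative and absolute solver tolerance (`> 0`).
#' @return Latent response at each requested `t`.
#' @export
latent_response_ode <- function(t, auc, params, tol = 1e-10) {
  stopifnot(inherits(params, "structural_params"))
  if (length(auc) != 1L || !is.finite(auc) || auc < 0)
    stop_validation("auc must be a single finite number >= 0")
  if (any(!is.finite(t)) || any(t < 0))
    stop_validation("t must be finite and >= 0")
  if (!is.numeric(tol) || tol <= 0) stop_validation("tol must be > 0")
  times <- sort(unique(c(0, t)))
  inh <- auc / (auc + params$eauc50)
  deriv <- function(time, state, p) {
    list(p$kin * (1 - inh) - p$kout * state[["R"]])
  }
  sol <- tryCatch(
    deSolve::ode(y = c(R = 1), times = times, func = deriv, parms = params,
                 method = "lsoda", rtol = tol, atol = tol),
    warning = function(w) stop_numerical("ODE solver warning: %s",
                                         conditionMessage(w)))
  if (attr(sol, "istate")[1L] < 0)
    stop_numerical("ODE solver failed (istate = %d)", attr(sol, "istate")[1L])
  sol[match(t, sol[, "time"]), "R"]
}

#' Predict the SOFA score at time t
#'
#' Deterministic structural prediction: baseline minus the standard-of-care
#' term minus the drug term.  The residual error \eqn{\epsilon} is *not*
#' added here; simulators add it.  A subject-level deviation `eta_k` shifts
#' the standard-of-care rate (`k + eta_k`); a negative effective rate is
#' allowed, in which case the predicted score can exceed baseline -- this
#' matches subjects whose organ function deteriorates despite care, and no
#' clipping is performed in the structural model.
#'
#' @inheritParams latent_response
#' @param base baseline SOFA score, `> 0`; scalar or same length as `t`.
#' @param eta_k additive subject deviation on `k`, 1/day (any real).
#' @return Predicted SOFA (real, unclipped), same length as `t`.
#' @export
predict_sofa <- function(t, base, auc, params, eta_k = 0) {
  stopifnot(inherits(params, "structural_params"))
  if (any(!is.finite(base)) || any(base <= 0))
    stop_validation("base must be finite and > 0")
  R <- latent_response(t, auc, params)
  fp <- params$f_placebo
  base - fp * base * (1 - exp(-(params$k + eta_k) * t)) -
    (1 - fp) * base * (1 - R)
}
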