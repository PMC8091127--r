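# sofaer

Exposure-response modelling of longitudinal SOFA scores in sepsis
trials.

## The problem

Early-phase sepsis trials read out on the Sequential Organ Failure
Assessment (SOFA) score, an integer 0–24 measure of organ dysfunction
recorded daily as patients recover under intensive care.  A Phase-IIa
dose-ranging study measured SOFA on days 0–8 in 34 subjects (10 placebo;
24 across 0.06/0.12/0.24 mg/kg q8h one-hour infusions) together with
each subject's steady-state exposure, the AUC over one 8-h dosing
interval.  The question is pharmacometric: how much of the observed SOFA
decline is standard care, how much is drug, and what exposure is enough?

`sofaer` implements the full pipeline for that analysis:

* **Structural model** — baseline minus an exponential standard-of-care
  term minus a drug term driven by a latent inhibitory indirect-response
  (turnover) process with `kin = kout` tied by the `R(0) = 1` initial
  condition:

  `SOFA(t) = Base − Fp·Base·(1 − exp(−(k+η)t)) − (1−Fp)·Base·(1 − R(t))`,
  `R(t) = 1 − I·(1 − exp(−kout·t))`, `I = AUC/(AUC + EAUC50)`.

* **NCA** — linear-trapezoid AUC(0–8h) from first- and last-dose
  concentration profiles, LLOQ handling, subject-level averaging.
* **Estimation** — FOCE / Laplace / adaptive Gauss–Hermite marginal
  likelihood for the nonlinear mixed-effects model, with standard
  errors, empirical Bayes estimates and shrinkage.
* **Diagnostics** — residual tables (PRED/IPRED/IWRES/linearised CWRES)
  and a prediction-corrected visual predictive check.
* **Simulation** — day-7 SOFA versus exposure profiles and
  placebo-versus-dose trajectory bands for dose selection.
* **Synthetic trial generator** — emulates the published population
  (truncated-rounded integer baselines, moment-matched lognormal
  exposures, optional dropout) plus a PK profile generator so the NCA
  layer is testable without patient data.
* **CLI** — `ser generate|nca|fit|gof|vpc|simulate` via the installed
  launcher `system.file("cli", "ser.R", package = "sofaer")`.

The methods vignette (`vignettes/sofaer-methods.Rmd`) documents the
model, the numerical choices, the generator calibration and the known
identifiability limitation of the `(kin, EAUC50)` pair at this design
size.

## Worked example

```r
library(sofaer)

truth  <- truth_params()        # final-model estimates as ground truth
design <- trial_design()        # 34 subjects, 10 placebo + 6/9/9
ds <- generate_trial(design, truth, seed = 42)
print(ds)
#> Trial dataset: 34 subjects (10 placebo), 306 observations
#>   arms: 0.06 n=6, 0.12 n=9, 0.24 n=9, placebo n=10

## exposure from synthetic concentration profiles, via the NCA module
profiles <- generate_pk_profiles(design, seed = 43)
expo <- exposure_from_profiles(profiles)
head(expo, 3)
#>          ID AUC_FIRST AUC_LAST AUC_USED
#> 1 0.06-0001   277.115  302.451  289.783
#> 2 0.06-0002   217.115  236.965  227.040
#> 3 0.06-0003   258.073  281.668  269.870

## FOCE fit of the mixed-effects model
fit <- fit_er_model(ds, init = list(f_placebo = 0.792, k = 0.263,
                                    kin = 0.0569, eauc50 = 1320,
                                    omega = 0.0794, sigma = 1.96),
                    config = list(seed = 1, starts = 2))
print(fit)
#> Exposure-response model fit (foce)
#>   OFV: 1157.2000   function evaluations: 1235
#>      PARAM     ESTIMATE   UNITS           SE    RSE_PCT SHRINK_PCT
#>  f_placebo   0.73610285         3.695536e-02   5.020407         NA
#>          k   0.34224394   1/day 4.243026e-02  12.397667  31.127131
#>        kin   0.03778235   1/day 4.784654e-02 126.637271         NA
#>     eauc50 509.96294260 h*ng/mL 1.484136e+03 291.028303         NA
#>      omega   0.08975221   1/day 2.801775e-02  31.216778         NA
#>      sigma   1.95295106    SOFA 8.986825e-02   4.601664   2.787155
```

The huge relative standard errors on `kin` and `eauc50` in a single
34-subject trial are real: those two parameters sit on a near-flat
likelihood ridge (only their combination is identified by 8 days of
data), while `f_placebo`, `k` and `sigma` are well determined.  See the
vignette for the analysis.

Diagnostics and dose-selection simulation:

```r
rt  <- residual_table(ds, fit)
gof <- plot_gof(rt)                               # 4 ggplot panels
vpc <- pcvpc(ds, fit, n_sim = 1000, seed = 2)
plot_vpc(vpc)

p <- simulate_day7_vs_auc(truth$params, truth$variance, baselines = 10,
                          auc_max = 5000, n_grid = 11, n_rep = 2e5,
                          seed = 7)[[1]]
p$P50[match(c(0, 1500, 5000), p$AUC)]
#> [1] 3.51 3.14 2.97
```

Day-7 median SOFA at baseline 10 drops 0.36 units from AUC 0 to
1500 h·ng/mL but only a further 0.18 from 1500 to 5000 — the
exposure-response is on its plateau at the highest studied dose, which
is the quantitative argument for 0.24 mg/kg.

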