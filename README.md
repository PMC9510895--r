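# doxpop

Mechanistic population-dynamics modelling of MCF-7 breast cancer cells
treated with doxorubicin, for quantitative cell biologists and
mathematical oncologists working with time-resolved microscopy counts.

Doxorubicin is a cytotoxic anthracycline; after each dose a fraction of
the population keeps proliferating while the rest is irreversibly
damaged and transitions from proliferation to drug-induced death. The
core model is a compartmental ODE system: untreated cells grow
logistically,

    dN/dt = g0 N (1 − N/θu),        N(0) = N0,

and dose *i* at time *t_i* splits the exposed population by a surviving
fraction f_s,i into surviving cells S and a new damaged subpopulation
D_i, after which

    dS/dt   = gs S (1 − N/θDox),
    dD_i/dt = [kd + (gd − kd) e^(−γ_d,i (t − t_i))] D_i (1 − N/θDox),

with total N = S + Σ D_i continuous across every dose. A *constant*
parameterization shares one f_s and one γ_d across doses; the
*adaptive* one gives each dose its own pair, representing acquired
chemoresistance.

The package covers the full analysis pipeline:

* `simulate_treatment()` — event-handling Dormand–Prince RK5(4)
  forward simulation (C++).
* `preprocess()` — truncation at confluence/major drops, media-handling
  discontinuity normalization, moving-median outlier removal.
* `fit_untreated()`, `fit_model()`, `apply_theta_dox_policy()` —
  bounded trust-region (Levenberg–Marquardt) least squares with the
  published tolerances; asymptotic parameter CIs and delta-method curve
  bands.
* `nrmse()`, `ccc()`, `r2_pcc()`, `wilcoxon_rank_sum()`,
  `compare_model_versions()` — quality of fit and the constant-vs-
  adaptive model selection rule (adaptive wins only when its NRMSE is
  significantly lower at 5%).
* `fit_formula()`, `lhs_sample()`, `simulate_band()` — empirical
  concentration–parameter formulas and Latin-hypercube uncertainty
  envelopes.
* `generate_replicate()`, `generate_experiment()` — a synthetic-data
  module emulating the three experimental designs (varying
  concentration, inter-treatment interval, dose number) with known
  ground truth.
* `run_pipeline()` / `doxpop_cli()` — end-to-end orchestration with
  seeded reproducibility (`inst/cli/doxpop.R` is the script shim).

## Worked example

Simulate one 75 nM single-dose replicate with 5% measurement noise,
clean it, and calibrate the single-dose model:

```r
library(doxpop)
world <- true_params_at(75)                      # generating parameters
sch   <- treatment_schedule(dose_times = 48, concentrations = 75)
rep1  <- generate_replicate(world, sch, cadence = 3, horizon = 504,
                            noise = noise_model(multiplicative_cv = 0.05,
                                                seed = 7))
clean <- preprocess(rep1$tc)
fit   <- fit_model(clean$tc, sch, mode = "constant", theta_u = 53873)
fit
#> <fit_result> constant, 8 free parameter(s), RSS = 2.079e+08
#>         g0         gs         gd         kd        fs1   gamma_d1         N0
#>  2.467e-02  1.791e-02  2.639e-02 -2.331e-02  1.899e-01  7.322e-02  2.074e+03
#>  theta_dox
#>  4.526e+04
#>   NRMSE 4.98%  R2 0.9949  PCC 0.9974  CCC 0.9974
```

The NRMSE (root-mean-square error as a percent of the mean observed
count) sits at the 5% noise floor and the concordance correlation
coefficient is 0.997, so the model reproduces the trajectory
essentially to measurement precision. The estimated surviving fraction
`fs1 = 0.19` (truth 0.22) says ~1 cell in 5 escaped the dose;
`kd = −0.023`/h is the asymptotic net death rate of the damaged cells.

```r
head(param_confidence_intervals(fit), 4)
#>   param    estimate           se       lower        upper at_bound unidentified
#> 1    g0  0.02467376 0.0056016416  0.01360778  0.035739733    FALSE        FALSE
#> 2    gs  0.01790718 0.0007075495  0.01650942  0.019304936    FALSE        FALSE
#> 3    gd  0.02639381 0.0401080825 -0.05283923  0.105626845     TRUE        FALSE
#> 4    kd -0.02330878 0.0102760343 -0.04360896 -0.003008594    FALSE        FALSE
```

`gd`'s interval crossing its bound (`at_bound`) is the expected
signature of the damaged-rate identifiability ridge — the fit is
excellent, but total counts alone constrain gd/kd/γ_d only jointly.

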