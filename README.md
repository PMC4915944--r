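# speedprior

Tools for studying how stimulus contrast biases perceived speed, and for
extracting the *slow-speed prior* that a Bayesian account says causes the
bias. The package is aimed at visual psychophysicists who run (or model)
2-AFC speed-matching experiments with drifting gratings: it simulates the
full experiment against a generative ideal observer, fits the observer
model back to the data with a fast summary-statistics method, and
validates the whole loop by parameter recovery on synthetic data.

## The model

The observer combines a Gaussian sensory likelihood of speed ν with a
semi-parametric slow-speed prior that is locally log-linear,
p(ν) ∝ exp(a(ν)·ν), with local slope a(ν) interpolated from four knots at
the reference speeds (1, 4, 8, 12 deg/s). The likelihood width is
separable,

    σ(ν, c) = g(ν) · h(c),      h(c) = 1 / (c^q / (c^q + c50^q) + 0.2),

so the posterior over perceived speed is Gaussian with

    E(ν̂) = ν + a(ν) σ²(ν, c),      Var(ν̂) = σ²(ν, c).

With a(ν) < 0 the percept is biased slow, more so at low contrast where σ
is large — the Thompson effect. On each trial the observer samples both
posteriors and picks the faster sample, so the psychometric function is
Φ((E₂−E₁)/√(σ₁²+σ₂²)).

Fitting uses only two numbers per condition: the mean PSE across QUEST
staircases, which pins the bias products a(ν)σ², and the across-staircase
PSE variance, which pins σ² itself through
σ²_PSE = α(σ₁²+σ₂²)/N (N = trials per staircase, α a procedure constant).
The prior is then reconstructed by integrating the fitted slopes:
p(ν) ∝ exp(∫a(ν)dν). A trial-level maximum-likelihood fit over the same 10
parameters (4 slopes, 4 widths, q, c50) serves as the reference method. An
optional temporal-filter "ratio model" front end (band-pass over low-pass,
each contrast-saturating) replaces ν by a nonlinear f(ν, c) to capture
speed-contrast interactions the prior alone cannot produce.

## Worked example

The `analysis/` scripts run the whole study end to end
(`Rscript analysis/01_simulate.R`, then `02_fit.R`, ...). In short:

```r
library(speedprior)

observer <- default_observer()          # slopes -0.3 -0.15 -0.08 -0.05
dataset  <- generate_dataset(observer, build_design(), master_seed = 42)
tab      <- pse_summary(dataset)        # 12 conditions x (mean PSE, variance)
compute_cdb(tab)                        # contrast-dependent bias per condition
```

The simulated experiment (300 staircases, 10,500 trials) shows the
Thompson effect: the observed CDB (PSE of the high-contrast test grating
over the reference speed) is below 1 in 11 of 12 conditions, e.g. 0.913 at
1 deg/s and 0.894 at 12 deg/s for the 3%/15% pair; the one exception
(1.013 at 8 deg/s, 15%/95%) is a condition whose true CDB is 0.996,
tipped over 1 by estimation noise. Fitting recovers the prior:

```r
alpha <- calibrate_alpha(dataset)       # 1.73 for this staircase procedure
fit <- fit_model(tab, fit_config(n_multistart = 20, alpha = alpha, n_trials = 35))
fit$observer$prior$knot_slopes
#> -0.403 -0.246 -0.0744 -0.042         # generator: -0.3 -0.15 -0.08 -0.05
reconstruct_prior(fit$observer$prior, c(1, 4, 8, 12))
```

Every slope comes back negative and in the generating order (weaker
slow-speed preference at higher speeds), with the CDB pattern fit at
R² = 0.87. On noise-free model-generated tables the fit is exact. The
fast method and the trial-level likelihood fit, run on the same synthetic
dataset (`analysis/03_method_agreement.R`), reconstruct priors with the
same density ordering at the four knots.

`analysis/04_ratio_model.R` characterizes the ratio front end: with the
combined-model parameters the output is 8.77 deg/s for a true 8 deg/s
grating at 95% contrast (near-veridical), while contrast still affects
the output by more than 1% up to 6.62 deg/s. On data generated with the
front end, the nested combined fit recovers its parameters exactly
(s = 0.50, k = 0.55, time-constant scale = 4.90; deviance 4.7e-06 versus
0.173 for the Bayesian-only fit). `analysis/05_report.R`
renders the CDB-versus-speed figure with model overlays and the
prior/g(ν)/h(c) component curves into `results/report/`.

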