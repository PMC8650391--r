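# latentresp

Latent-variable analysis of composite responder endpoints, with the
standard collapsed-binary analysis and pilot-driven sample-size
calculation alongside.

## The problem

Trials in rheumatology (and beyond) often use *composite responder
endpoints*: a participant counts as a responder only if they
simultaneously clear thresholds on one or two continuous measures and, in
many endpoints, meet a binary requirement.  An SRI-type lupus endpoint,
for example, requires a disease-activity improvement of at least 4 points,
no meaningful worsening of the physician's global assessment (change below
0.3), and a sustained steroid taper.  The routine analysis collapses all
of this into a single 0/1 indicator, discarding how close each continuous
reading was to its threshold, and pays for that simplicity with badly
inflated variance — wider confidence intervals, lower power, larger
trials.

`latentresp` implements the *augmented* analysis: the components are
modelled jointly with a latent Gaussian model

- continuous component *j*:  `Y_j = α_j + β_j·arm + γ_j·baseline_j + σ_j·ε_j`
- binary component (probit): `Y_b = 1{α_b + β_b·arm + ε_b > 0}`
- `(ε_1, …, ε_b)` jointly standard normal with correlation matrix `R`,

and the per-arm response probability is obtained as the (deterministically
computed) multivariate-normal box probability of the responder region,
averaged over the observed baselines (marginal standardisation).  Effects
are reported exactly as in the standard analysis — risk difference, risk
ratio, odds ratio with 95% intervals — but estimated with the full
precision of the continuous data.  The package also provides the collapsed
analysis itself, goodness-of-fit diagnostics, a seeded synthetic-trial
generator, a power/sample-size module, and a command-line interface.

## Worked example

A small synthetic trial (180 subjects, generated from the package's
SLE-like preset — clearly labelled synthetic, no patient data anywhere) is
bundled:

```r
library(latentresp)

spec  <- endpoint_spec(n_cont = 2, has_binary = TRUE,
                       thresholds = c(-4, 0.3), inclusive = c(TRUE, FALSE))
csv   <- system.file("extdata", "synthetic_sle_trial.csv", package = "latentresp")
trial <- read_dataset(csv, spec)

fit <- fit_latent_model(trial)
aug <- augmented_effects(fit)          # latent-model route, delta-method CIs
bin <- binary_effects(trial)           # collapsed route, Wald CIs
print(aug); print(bin)
```

```
Treatment effects (augmented, delta 95% CIs)
  P(response | control)   = 0.1832
  P(response | treatment) = 0.3167
  log-OR   0.7258  [0.2136, 1.2381]
  log-RR   0.5474  [0.1552, 0.9396]
  RD       0.1335  [0.0407, 0.2263]
Treatment effects (binary-unadjusted, wald 95% CIs)
  P(response | control)   = 0.2111
  P(response | treatment) = 0.3222
  log-OR   0.5747  [-0.0974, 1.2468]
  log-RR   0.4229  [-0.0764, 0.9221]
  RD       0.1111  [-0.0171, 0.2393]
```

Both routes estimate a treatment benefit of similar size (a risk
difference of 0.11–0.13), but the augmented log-OR interval is 24%
narrower (`efficiency_report(diff(aug$ci_log_or), diff(bin$ci_log_or))`)
— on this dataset the collapsed analysis cannot even exclude a null
effect while the augmented one can.  That precision gain is the whole
point of the method.  Sizing a future trial from these pilot estimates:

```r
ss <- power_curve(delta = bin$rd,
                  sigma2_tot_aug = pilot_variance(aug),
                  sigma2_tot_bin = pilot_variance(bin))
print(ss)
```

```
Sample size for one-sided alpha 0.05, target power 80%, delta 0.1111
  augmented route: sigma2_tot 0.20192 -> n = 102 per arm
  binary route:    sigma2_tot 0.38494 -> n = 193 per arm
```

`gof_residuals(fit)` reports a Kolmogorov–Smirnov distance of 0.046
(df = 2) for the squared Mahalanobis residuals of the continuous block
against their chi-squared reference — no evidence of misfit, as expected
for data generated from the model.

The same analyses are available from the shell:

```sh
Rscript inst/cli/latentresp-cli.R simulate --n-per-arm 90 --seed 1 --out trial.csv
Rscript inst/cli/latentresp-cli.R analyse --data trial.csv --ncont 2 \
    --tau=-4,0.3 --out report.json
Rscript inst/cli/latentresp-cli.R samplesize --p0 0.256 --p1 0.395
```

## Documentation

See the methods vignette
(`vignettes/latent-composite-endpoints.Rmd`) for the model, its
assumptions, the numerical choices, what the synthetic generator does and
does not emulate, and known limitations.
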