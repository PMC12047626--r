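# metagrt

Multidimensional signal detection analysis of how tip-of-the-tongue (TOT)
and feeling-of-knowing (FOK) states modulate the metacognitive sensitivity
of post-decision confidence.

In two-stage metamemory experiments, participants who fail to recall a
target report a metacognitive state (TOT yes/no or FOK high/low), make a
two-choice recognition decision, and rate their confidence in it. `metagrt`
asks whether confidence *tracks recognition accuracy better* when the
metacognitive state is strong, and answers it with a bivariate general
recognition theory (GRT) model with individual differences:

* each stimulus condition — correct name, incorrect name, catch (no true
  answer) — is a bivariate Gaussian over recognition evidence *x* and
  metacognitive evidence *y*, with the catch condition anchored at the
  origin and all marginal variances fixed at 1; free parameters are the
  famous-condition means (μ\_x, μ\_y), the per-stimulus correlations ρ\_s,
  and per-participant scalings (κ\_i, λ\_i) plus criteria
  (c\_y; c\_x1 < c\_x2);
* the model is fitted by multinomial maximum likelihood over every
  participant's 3 × 6 count table, with 100 random restarts;
* from the fit, a **type-2 sensitivity-vs-metacognition (SvM) curve** is
  derived: at each evidence level *y*, the relative likelihood
  L(y) = ½[N(y; μ\_y,corr, 1) + N(y; μ\_y,inc, 1)] / N(y; 0, 1) of a true
  metacognitive state (the x-axis), and the conditional meta-d′ — the
  sensitivity of the equal-variance SDT observer that best reproduces the
  model-implied confidence probabilities at that height (the y-axis) —
  together with the optimal observer's objective criterion y\* where
  L(y\*) = 1;
* pointwise 99% percentile bands come from a parametric bootstrap
  (simulate from the fit, refit, rebuild the curve, compare on a common
  relative-likelihood grid).

A rising curve with meta-d′ > 0 left of y\* means confidence sensitivity
grows with TOT/FOK strength while some sensitivity survives in the state's
absence.

The package also ships the surrounding pipeline: trial-level file I/O and
validation, aggregation to count tables, participant exclusion rules,
confidence reclassification, per-state mean confidence with Friedman
tests, a synthetic-study generator with known ground truth for
parameter-recovery studies, ggplot2 `autoplot()` methods, and broom-style
`tidy()` / `glance()` methods.

## Worked example

```r
library(metagrt)

study  <- generate_study(study_config(n_participants = 10, seed = 42))
counts <- aggregate_counts(study$trials, judgment = "tot")
fit    <- fit_grt_wind(counts, n_restarts = 20, seed = 7)
fit
#> Decision-space model fit (GRT with individual differences)
#>   participants: 10   judgment: tot
#>   log-likelihood: -5989.8062  (best of 20 restarts, 13 converged)
#>   variance accounted for: 99.16%
#>   group means / correlations:
#>        stimulus      mu_x     mu_y          rho
#>    correct_name  1.126121 1.080212  0.550158969
#>  incorrect_name -1.062068 1.054062 -0.537644873
#>           catch  0.000000 0.000000  0.008019623
```

The generating model had μ\_x = ±1, μ\_y = 1, ρ = (+0.5, −0.5, 0): the fit
recovers the means within ~0.13 and the correlations within ~0.05, and
accounts for 99.2% of the variance in the observed cell proportions.

```r
curve <- build_svm_curve(fit)
glance(curve)
#> # A tibble: 1 × 6
#>   y_star L_star meta_d_at_y_star meta_d_min meta_d_max n_grid
#>    <dbl>  <dbl>            <dbl>      <dbl>      <dbl>  <int>
#> 1  0.534      1             1.91      -2.67       6.51    201
autoplot(curve)   # rising meta-d' over relative likelihood, y* at L = 1
```

The curve rises monotonically: conditional meta-d′ is already 1.91 at the
objective criterion and keeps growing with state strength — the signature
of metacognitive states sharpening confidence sensitivity. The
complementary descriptive comparison shows the same direction on the raw
scale:

```r
de <- confidence_by_state(study$trials, "tot")
de$summary
#> # A tibble: 2 × 5
#>   judgment state    mean    sd     n
#> 1 tot      present  2.59 0.412    10
#> 2 tot      absent   1.99 0.399    10
de$test
#>   statistic    df p.value     n     k method
#> 1        10     1 0.00157    10     2 Friedman rank sum test
```

Bootstrap bands and the full pipeline:

```r
band <- bootstrap_svm_band(fit, n_boot = 1000, level = 0.99, seed = 11)
autoplot(curve, band = band)

run_pipeline(pipeline_config(study = study_config(), out_dir = "results",
                             judgment = "tot", seed = 1))
```

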