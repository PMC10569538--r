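# interanimal

Noise-corrected inter-animal consistency and model neural predictivity for
trial-structured population recordings.

## The problem

Repeated presentations of the same stimulus never evoke the same neural
response twice. That trial-to-trial noise caps the correlation any
predictor — another animal's population, or a candidate model — can reach
against measured responses, so raw predictivity numbers conflate model
quality with recording reliability. This package estimates predictivity
*relative to that ceiling*: it asks how well a mapped source population
predicts the target's **reliable** signal, so that a perfect model of the
signal scores 1 whatever the noise level. It is written for systems
neuroscientists comparing population recordings across animals (e.g. mouse
visual cortex viewing natural scenes) and benchmarking candidate encoding
models against the inter-animal ceiling.

## The estimator

For source A, target B and mapping class $M$ (identity, one-to-one, ridge,
or 25-component PLS), trials are split into random halves $s_1, s_2$ and
averaged; the target quantity
$\mathrm{Corr}\big(M(t^A;t^B)_{\mathrm{test}},\, t^B_{\mathrm{test}}\big)$
on true responses $t$ is estimated by

$$\frac{\mathrm{Corr}\big(M(s^A_1; s^B_1)_{\mathrm{test}},\ s^B_{2,\mathrm{test}}\big)}
       {\sqrt{\widetilde{\mathrm{Corr}}\big(M(s^A_1;s^B_1)_{\mathrm{test}},\, M(s^A_2;s^B_2)_{\mathrm{test}}\big)\,
        \widetilde{\mathrm{Corr}}\big(s^B_{1,\mathrm{test}},\, s^B_{2,\mathrm{test}}\big)}},$$

with $\widetilde{\mathrm{Corr}}(x,y) = \tfrac{2\,\mathrm{Corr}(x,y)}{1+\mathrm{Corr}(x,y)}$
the Spearman–Brown correction applied to each denominator reliability. The
ratio is averaged per target unit over bootstrapped trial halves and
train/test stimulus splits, units are concatenated across target animals,
and the median ± s.e.m. across units is reported. Replacing the source with
deterministic model features gives the model's neural predictivity; the same
correction applied to RDM correlations gives noise-ceiling RSA. A built-in
cohort simulator with analytic ground truth (closed-form split-half
reliability $v/(v + w/(n/2))$) makes every estimator testable end to end,
and reliability / behavioral-modulation / temporal-window / specimen filters
implement the standard dataset conditioning.

## Worked example

```r
library(interanimal)

# three simulated animals sharing a latent signal: 118 natural-scene-like
# stimuli, 50 trials, 60 units each, trial noise sd 1
sim <- generate_cohort(n_animals = 3, n_units = 60, n_stimuli = 118,
                       n_trials = 50, noise_sd = 1, seed = 1)
sim$recordings[[1]]
#> <population_recording> animal animal_01, area VISp
#>   118 stimuli x 50 trials x 60 units

# pooled-source inter-animal ceiling: hold out each animal, map to it from
# the concatenated units of the others with PLS
results <- pooled_consistency(sim$recordings, spec = mapping_spec("pls"),
                              half_plan = split_half_plan(20, seed = 2),
                              split_plan = stimulus_split_plan(n_splits = 5, seed = 3))
agg <- aggregate_units(results)
#> pooled PLS ceiling: median 0.980 +/- 0.001 s.e.m. over 180 units

# score two synthetic model layers against the same cohort
feats <- generate_model_features(sim$ground_truth,
  list(faithful = list(n_features = 40, corruption = 0),
       degraded = list(n_features = 40, corruption = 0.7)), seed = 4)
pred <- model_neural_predictivity(feats, sim$recordings, mapping_spec("pls"),
                                  split_half_plan(10, seed = 5),
                                  stimulus_split_plan(n_splits = 3, seed = 6))
tidy(pred)
#> # A tibble: 2 x 5
#>   layer    median      sem n_units n_dropped
#>   <chr>     <dbl>    <dbl>   <int>     <int>
#> 1 faithful  0.984 0.000516     180         0
#> 2 degraded  0.382 0.00896      180         0
pred$best_layer
#> [1] "faithful"
```

A layer that is an invertible linear transform of the shared signal reaches
the ceiling (0.98, i.e. ~1 after noise correction); a 70%-corrupted layer
drops to 0.38. `autoplot()` on any result draws the per-unit distribution or
per-layer summary; `tidy()`/`glance()` return the underlying tibbles.

A command-line pipeline (`inst/exec/interanimal`) chains
`simulate → select-units → consistency / rsa / predictivity / transfer →
extrapolate`, driven by YAML configs with mandatory seeds, writing CSV/JSON
artifacts plus a run manifest.

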