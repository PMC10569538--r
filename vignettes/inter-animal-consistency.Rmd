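---
title: "Noise-corrected inter-animal consistency and model predictivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-corrected inter-animal consistency and model predictivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interanimal)
```

## The estimation problem

Trial-to-trial noise puts a hard ceiling on how well anything — another
animal, or a model — can appear to predict a neural population. If animal B's
responses are only 70% reliable across repeated presentations, even a perfect
model of B's reliable signal cannot correlate with B's measured responses
beyond that reliability. This package estimates how well one population
predicts another *after* removing that ceiling, so that a perfect model of
the reliable signal scores 1 regardless of the noise level.

Write $t^p$ for the true (noiseless) response of animal $p$ across a stimulus
set, and $s^p_j$ for the average of the $j$-th half of its trials. The target
quantity for a source animal A, target animal B and mapping class $M$ is

$$\mathrm{Corr}\!\left(M(t^A; t^B)_{\mathrm{test}},\ t^B_{\mathrm{test}}\right),$$

the test-set correlation between mapped true source responses and true target
responses. Neither $t^A$ nor $t^B$ is observable, so the package estimates it
with the ratio

$$\frac{\mathrm{Corr}\!\left(M(s^A_1; s^B_1)_{\mathrm{test}},\ s^B_{2,\mathrm{test}}\right)}
       {\sqrt{\widetilde{\mathrm{Corr}}\!\left(M(s^A_1; s^B_1)_{\mathrm{test}},\ M(s^A_2; s^B_2)_{\mathrm{test}}\right)
       \times \widetilde{\mathrm{Corr}}\!\left(s^B_{1,\mathrm{test}},\ s^B_{2,\mathrm{test}}\right)}},$$

where $\widetilde{\mathrm{Corr}}(x, y) = 2\,\mathrm{Corr}(x,y) / (1 +
\mathrm{Corr}(x,y))$ is the Spearman–Brown correction. The numerator is the
raw cross-half predictivity; the denominator combines the mapping's own
reliability (agreement between predictions trained on the two half-splits)
with the target's internal consistency. The derivation rests on transitivity
of positive correlations across large stimulus sets and on the Gaussian-noise
identity

$$\mathrm{Corr}(s_1, s_2) \approx \mathrm{Corr}(t, s_2)^2,$$

which the test suite verifies directly on simulated data at 10,000 stimuli
(`split_trials()` plus the simulator's ground truth; observed gaps are well
under 0.02).

The same ratio with the source replaced by a deterministic model feature
matrix is the model's *neural predictivity* (`model_neural_predictivity()`);
because model features have no trial noise, their mapping reliability term
plays the role of the source reliability, and a model of the true signal
again scores 1. The RSA variant (`noise_corrected_rsa()`) applies the
identical correction structure to Pearson correlations of RDM upper
triangles instead of per-unit response correlations, with the source
reliability fixed at exactly 1 in model mode; we use the square-root form of
the denominator there as well, since only that form recovers 1 when the
model features equal the true responses.

## Averaging order and summaries

For each bootstrap resample of the trial halves (default 100) and each
train/test stimulus split (default 10 random 50/50 partitions), the corrected
ratio is computed per target unit; the *ratio* is averaged per unit over
bootstraps and splits, units are concatenated across target animals, and the
median and s.e.m. (standard deviation across units divided by $\sqrt{n}$) are
reported. Each target unit therefore contributes one averaged value — the
median is never taken inside the bootstrap loop.

Unit-bootstraps whose denominator terms are non-positive or undefined are
excluded from that unit's average (the ratio is unstable at near-zero
reliability); a unit with more than half of its bootstraps excluded is
dropped entirely and reported in the result's excluded-unit log. The
reliability filter described below keeps analyses out of this regime in the
first place.

## Mapping transforms

Four mapping classes are available through `mapping_spec()`:

* **identity** — pass-through; requires equal unit counts; used for RSA.
* **one_to_one** — each target unit is predicted by its single
  best-correlated source unit (signed Pearson maximum on the training
  stimuli, ties to the lowest source index, then a univariate least-squares
  rescaling). An `one_to_one_absolute` flag switches the screen to $|r|$.
* **ridge** — multivariate L2-penalized regression, penalty 1 by default on
  the squared-coefficient scale, intercept unpenalized, no feature
  standardization (solved in closed form via centered normal equations).
* **pls** — partial least squares regression with 25 components by default
  (NIPALS, via mixOmics), fit with an intercept and no standardization.

The PLS component count is capped at `min(25, n_train_stimuli - 1,
n_source_units, rank of the training design)`, and backs off further if the
factorization fails at a boundary count; cap events are recorded on the
fitted object. Zero-variance source units are dropped before multivariate
fits; zero-variance target units get mean predictions (PLS) or flagged
undefined assignments (one-to-one). Intercepts and the no-standardization
default are explicit choices — responses enter on a common trial-averaged
scale, and both are overridable by pre-transforming the matrices.

On shared-signal synthetic cohorts PLS attains the highest corrected
consistency and one-to-one the lowest, mirroring the qualitative ordering
such mapping comparisons show on cortical data; the acceptance suite asserts
`median(one_to_one) <= median(pls) + 0.02`.

## What the simulator emulates

`generate_cohort()` draws a shared latent signal (default 20 dimensions)
across stimuli, mixes it into each animal's units with per-animal Gaussian
weights scaled so unit signal variance is ~1, optionally applies a pointwise
nonlinearity (`rectify`, `squash`) to create relations a linear map cannot
fully capture, and adds i.i.d. Gaussian trial noise. Defaults mirror a
natural-scene protocol: 118 stimuli, 50 trials, with per-unit noise either
fixed or spread over a range so reliabilities straddle the 0.3 selection
threshold. Gaussian noise is assumed because the correction's approximations
hold exactly in that case; heteroscedastic per-unit noise is supported, but
correlated noise, calcium-indicator dynamics, spiking statistics and
behavioral covariates beyond a per-presentation scalar are not simulated.
Passing tests on this simulator therefore demonstrate estimator correctness
under the derivation's own assumptions — not robustness to every property of
real recordings.

`analytic_split_half_consistency(v, w, n)` $= v / (v + w/(n/2))$ is the
closed-form expected split-half correlation used as the oracle throughout:
the simulator's empirical reliabilities converge to it as stimuli grow
(verified at 5,000 stimuli within 0.02), and `generate_timebinned_recording()`
inverts it to plant arbitrary per-bin reliability profiles for testing the
temporal window selector. `generate_model_features()` produces feature
layers interpolating between an invertible linear transform of the latent
(corruption 0 — a perfect linear model) and pure noise (corruption 1), with
`sqrt(1-c)`/`sqrt(c)` weights keeping variance comparable across levels.

One master seed drives everything; per-animal and per-bootstrap substreams
are derived deterministically from it, so all generators and estimators are
bit-reproducible.

## Dataset conditioning

`calcium_unit_filter()` keeps units whose Spearman–Brown-corrected split-half
consistency (averaged over 100 bootstraps) reaches 0.3 and whose peak
response to the preferred stimulus (maximal trial-mean response, ties to the
lowest index) is not significantly modulated by a behavioral covariate such
as running speed. No specific modulation test is prescribed by the procedure
this emulates, so the package uses a two-sided permutation test (1,000
permutations) on the Spearman correlation between covariate and single-trial
responses, keeping units with p > 0.05 — an explicit stand-in, reported as
such in the selection report.

`neuropixels_window_select()` finds, for binned recordings (10-ms bins up to
250 ms), the largest contiguous run of bins whose population-median
split-half consistency reaches 0.3, breaking ties toward the earlier window,
and averages responses over it. `specimen_percentile_filter()` keeps
specimens at or above the 75th percentile unit count within each area, using
linear interpolation between order statistics (counts [4, 8, 15, 16] give a
threshold of 15.25, keeping only the largest specimen) — the inclusive
comparison reads "at least" literally.

## Extrapolation

`subsampled_consistency()` recomputes the pooled-source ceiling at a series
of unit fractions, and `fit_loglinear_extrapolation()` fits
$f(n) = a \log_{10}(n) + b$ by least squares, projecting how the ceiling
grows with more recorded units. Predictions are clipped at 1 on report with
an explicit flag, since the fit is unbounded. The two-point recovery and
noiseless-residual checks are exact.

## Architecture family and objectives

`build_streamnet_config()` encodes the shallow multi-stream convolutional
family: shallow (64, 11, 4, 2) + stride-2 max pool, per-stream intermediate
blocks [(192, 5, 1, 2) + pool, (384, 3, 1, 1)], one deep convolution per
stream — (256, 3, 1, 1) from intermediate, (256, 3, 2, 0) when fed directly
from shallow — and a readout that average-pools to 6 × 6, flattens and
applies a linear layer. The longest convolutional path is 4. At 64-px input
the shape calculator reproduces the module output sizes 7, 3 and 3 via
`floor((W + 2P - K)/S) + 1` arithmetic, and `extract_untrained_features()`
instantiates the stack with seeded Gaussian fan-in-scaled weights (the
untrained initialization is the package's own choice) and returns per-module
activations whose shapes match the calculator at any valid resolution.

The training objectives are implemented as standalone, desk-scale loss
computations with their printed normalizations — cross-entropy; the sparse
autoencoder loss with $1/(2 \cdot 64^2)$ reconstruction and $\lambda/128$
sparsity scaling; depth regression on per-map standardized targets;
instance recognition with a memory bank ($\tau = 0.07$, momentum 0.5 bank
updates; the normalization constant $Z$ is frozen from a sampled estimate
$N \cdot \overline{\exp(u \cdot z/\tau)}$, overridable, and documented as a
stand-in); the momentum-queue InfoNCE loss ($\tau = 0.2$, enqueue/dequeue and
0.999 key-encoder updates); the batchwise contrastive loss over paired
augmentations ($\tau = 0.1$); negative-cosine with stop-gradient semantics
(a value contract only — no gradients here); the cross-correlation
redundancy-reduction loss ($\lambda = 0.0051$, column-norm normalization
without batch centering, as printed); and the
variance-invariance-covariance objective, whose source names its three terms
without printing a formula — implemented with the reference coefficients
(25, 25, 1), explicitly not taken from that source. Training loops,
optimizers and augmentation stacks are out of scope by design: the losses
are validated against closed forms (uniform logits give $\ln C$; identical
batch embeddings give $\log(2N-1)$; an orthogonal negative queue gives an
explicit softmax value), not by training.

Desk-scale defaults shrink the bank/queue sizes; the documented reference
configuration keeps the original values ($m = 4096$, $K = 65{,}536$).

## Transfer readout

`linear_transfer_evaluation()` reduces features to at most 1,000 dimensions
by PCA — fit on the training portion of each outer split only, a leakage
guard the underlying protocol leaves unspecified — then fits a linear
max-margin classifier with cost $C$ chosen by inner 5-fold cross-validation
over the 31-point grid from $10^{-8}$ to $5 \times 10^8$
(`regularization_grid()`), or a ridge regression with $\alpha = 1/C$ over
the same grid. Scores are mean accuracy or mean Pearson correlation over ten
category-balanced outer splits; best-layer selection uses the same splits as
reporting, matching the max-over-layers convention.

## Numerical choices and problem sizes

Correlations of constant vectors are undefined and propagate as exclusions,
never silent zeros. Trial halves are resampled independently per bootstrap
rather than fixed even/odd; odd trial counts drop one random trial, logged.
RDM dissimilarity defaults to one minus Pearson correlation across units
(the metric is not pinned down by the protocols this package follows;
Euclidean is available). The denominator radical covers the product of both
corrected terms by default, with `denominator_form = "sqrt_mapping_only"`
for sensitivity analysis — at high reliabilities the two readings differ
negligibly, and only the product form recovers exactly 1 in the noiseless
limit.

The acceptance computations run the full 3-animal, 100-unit, 118-stimulus,
50-trial cohort with 20 bootstrap half-splits and 5 stimulus splits (the
package defaults remain 100 and 10); at these sizes the pooled PLS median is
stable to ~0.005 and completes in a few minutes on one core. The estimator
carries a small downward bias of order $1 - \rho_{half}/\rho_{full}$
(~1–2% at 50 trials) because the numerator uses half-trial averages while
the Spearman–Brown terms correct to full-trial reliability; this is well
inside the acceptance band and vanishes as trials grow.

## Known limitations

Linear (or single-unit) mappings only — the ceiling is defined relative to a
mapping class, and an unconstrained nonlinear class would make it vacuous.
No correlated or non-Gaussian noise in the simulator; no real-data loaders
(the container format is the package's own directory layout); RSA mode
yields one value per animal, so cohort-level RSA medians need several
animals to be meaningful; and the untrained feature extractor is a compact
reference implementation intended for correctness tests and small stimulus
sets, not large-scale feature dumps.
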