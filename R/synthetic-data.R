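#' Simulate a multi-animal cohort with known signal and noise structure
#'
#' Generates trial-structured recordings for several animals whose true
#' (noiseless) responses are linear mixtures of a shared low-dimensional
#' latent signal, plus i.i.d. Gaussian trial noise. Defaults mirror a natural
#' scene protocol of 118 images shown 50 times each. Mixing weights are drawn
#' `N(0, 1/n_latent)` so each unit's signal variance is ~1 regardless of the
#' latent dimensionality; `noise_sd = 1` then puts the default units in a
#' high-reliability regime, and a range (e.g. `c(0.3, 3)`) spreads units
#' across reliabilities.
#'
#' @param n_animals,n_units,n_stimuli,n_trials,n_latent Cohort dimensions.
#'   `n_trials` must be at least 2.
#' @param noise_sd Per-trial Gaussian noise standard deviation: a scalar
#'   (same for every unit), a length-2 range (per-unit values drawn uniformly
#'   within it), or a length-`n_units` vector.
#' @param nonlinearity Optional pointwise nonlinearity applied to the true
#'   responses: `"none"`, `"rectify"` (half-wave) or `"squash"` (tanh). Used
#'   to create inter-animal relations a linear map cannot fully capture.
#' @param shared_signal If `FALSE`, each animal gets an independent latent,
#'   making populations statistically unrelated (a null cohort).
#' @param seed Master seed; per-animal substreams are derived from it, so the
#'   output is bit-reproducible.
#'
#' @return A list with `recordings` (list of [population_recording()]) and
#'   `ground_truth` (class `ground_truth`: `latent`, per-animal `mixing` and
#'   `true_responses`, `noise_sd`, `nonlinearity`).
#' @export
generate_cohort <- function(n_animals = 3, n_units = 60, n_stimuli = 118,
                            n_trials = 50, n_latent = 20, noise_sd = 1,
                            nonlinearity = c("none", "rectify", "squash"),
                            shared_signal = TRUE, seed = 1) {
  n_animals <- check_count(n_animals, "n_animals")
  n_units <- check_count(n_units, "n_units")
  n_stimuli <- check_count(n_stimuli, "n_stimuli")
  n_trials <- check_count(n_trials, "n_trials", min = 2)
  n_latent <- check_count(n_latent, "n_latent")
  nonlinearity <- match.arg(nonlinearity)
  noise_sd_spec <- noise_sd
  if (any(noise_sd < 0)) abort("`noise_sd` must be nonnegative.")

  latent <- with_seed(derive_seed(seed, 0),
                      matrix(rnorm(n_stimuli * n_latent), n_stimuli, n_latent))
  recordings <- vector("list", n_animals)
  mixing <- vector("list", n_animals)
  true_responses <- vector("list", n_animals)
  noise_sds <- vector("list", n_animals)

  for (p in seq_len(n_animals)) {
    sub <- derive_seed(seed, p)
    lat <- if (shared_signal) latent else {
      with_seed(derive_seed(seed, 10000 + p),
                matrix(rnorm(n_stimuli * n_latent), n_stimuli, n_latent))
    }
    out <- with_seed(sub, {
      W <- matrix(rnorm(n_latent * n_units, sd = 1 / sqrt(n_latent)),
                  n_latent, n_units)
      sds <- expand_noise_sd(noise_sd_spec, n_units)
      t_p <- apply_nonlinearity(lat %*% W, nonlinearity)
      noise <- array(rnorm(n_stimuli * n_trials * n_units), c(n_stimuli, n_trials, n_units))
      noise <- sweep(noise, 3, sds, `*`)
      resp <- array(rep(t_p, each = 1), c(n_stimuli, 1, n_units))[, rep(1, n_trials), , drop = FALSE] + noise
      list(W = W, sds = sds, t_p = t_p, resp = resp)
    })
    mixing[[p]] <- out$W
    noise_sds[[p]] <- out$sds
    true_responses[[p]] <- out$t_p
    recordings[[p]] <- population_recording(out$resp, animal_id = sprintf("animal_%02d", p))
  }

  gt <- structure(
    list(latent = if (shared_signal) latent else NULL,
         mixing = mixing, true_responses = true_responses,
         noise_sd = noise_sds, nonlinearity = nonlinearity,
         shared_signal = shared_signal, seed = seed),
    class = "ground_truth"
  )
  list(recordings = recordings, ground_truth = gt)
}

expand_noise_sd <- function(noise_sd, n_units) {
  if (length(noise_sd) == 1) rep(noise_sd, n_units)
  else if (length(noise_sd) == 2) runif(n_units, noise_sd[1], noise_sd[2])
  else if (length(noise_sd) == n_units) as.numeric(noise_sd)
  else abort("`noise_sd` must be a scalar, a length-2 range, or one value per unit.")
}

apply_nonlinearity <- function(x, tag) {
  switch(tag, none = x, rectify = pmax(x, 0), squash = tanh(x))
}

#' Expected split-half correlation under additive Gaussian noise
#'
#' Closed form for the Pearson correlation across stimuli between two averages
#' of `n_trials / 2` independent noisy trials each: `v / (v + w / (n/2))`
#' where `v` is the across-stimulus signal variance and `w` the per-trial
#' noise variance. Serves as the analytic oracle for the simulator's
#' split-half reliabilities.
#'
#' @param signal_var Across-stimulus variance of the true response (> 0).
#' @param noise_var Per-trial noise variance (>= 0).
#' @param n_trials Total number of trials split into two halves (>= 2).
#' @return Expected split-half correlation in `[0, 1]`.
#' @export
analytic_split_half_consistency <- function(signal_var, noise_var, n_trials) {
  if (signal_var <= 0) abort("`signal_var` must be positive.")
  if (noise_var < 0) abort("`noise_var` must be nonnegative.")
  n_trials <- check_count(n_trials, "n_trials", min = 2)
  half <- n_trials / 2
  signal_var / (signal_var + noise_var / half)
}

#' Simulate a time-binned recording with a per-bin reliability profile
#'
#' Produces a `stimuli x trials x units x bins` recording whose expected
#' per-unit split-half consistency in bin `k` equals `reliability_profile[k]`
#' (signal variance fixed at 1; per-bin noise variance solved from
#' [analytic_split_half_consistency()]). Emulates binned spiking responses
#' (10-ms bins up to 250 ms) and is used to exercise temporal window
#' selection.
#'
#' @param reliability_profile Numeric vector in `[0, 1)`, one target expected
#'   split-half consistency per bin.
#' @param n_bins Number of bins; must equal `length(reliability_profile)`.
#' @param bin_ms Bin width in milliseconds (default 10); `n_bins * bin_ms`
#'   must not exceed `max_ms`.
#' @param max_ms Maximum covered latency (default 250 ms).
#' @inheritParams generate_cohort
#' @return A [population_recording()] with a time axis, plus the latent
#'   signal in attribute `"true_responses"` (`stimuli x units`, shared across
#'   bins).
#' @export
generate_timebinned_recording <- function(n_units = 20, n_stimuli = 118,
                                          n_trials = 50,
                                          reliability_profile,
                                          n_bins = length(reliability_profile),
                                          bin_ms = 10, max_ms = 250, seed = 1) {
  n_bins <- check_count(n_bins, "n_bins")
  if (length(reliability_profile) != n_bins) {
    abort("`reliability_profile` length must equal `n_bins`.")
  }
  if (any(reliability_profile < 0 | reliability_profile >= 1)) {
    abort("`reliability_profile` values must lie in [0, 1).")
  }
  if (n_bins * bin_ms > max_ms) {
    abort(sprintf("n_bins * bin_ms = %d exceeds max_ms = %d.", n_bins * bin_ms, max_ms))
  }
  n_units <- check_count(n_units, "n_units")
  n_stimuli <- check_count(n_stimuli, "n_stimuli")
  n_trials <- check_count(n_trials, "n_trials", min = 2)

  half <- n_trials / 2
  prof <- pmax(reliability_profile, 1e-6)
  noise_var <- (1 - prof) / prof * half  # solves r = 1 / (1 + w / half)

  with_seed(derive_seed(seed, 77), {
    t_p <- matrix(rnorm(n_stimuli * n_units), n_stimuli, n_units)
    resp <- array(0, c(n_stimuli, n_trials, n_units, n_bins))
    for (k in seq_len(n_bins)) {
      noise <- array(rnorm(n_stimuli * n_trials * n_units, sd = sqrt(noise_var[k])),
                     c(n_stimuli, n_trials, n_units))
      resp[, , , k] <- array(t_p[rep(seq_len(n_stimuli), n_trials), ],
                             c(n_stimuli, n_trials, n_units)) + noise
    }
    rec <- population_recording(resp, animal_id = "binned_01", time_bin_ms = bin_ms)
    attr(rec, "true_responses") <- t_p
    rec
  })
}

#' Generate per-layer model feature matrices from simulator ground truth
#'
#' Builds deterministic `stimuli x features` matrices at controllable
#' fidelity: corruption 0 is an invertible linear transform of the cohort's
#' latent signal (a perfect linear model of the reliable signal), corruption
#' 1 is pure noise, and intermediate levels interpolate as
#' `sqrt(1 - c) * signal + sqrt(c) * noise` so the feature variance stays
#' comparable across levels.
#'
#' @param ground_truth A `ground_truth` object from [generate_cohort()] (must
#'   carry a shared latent).
#' @param layer_specs List of `list(n_features =, corruption =)` entries, one
#'   per layer; corruption must lie in `[0, 1]` and `n_features` must be at
#'   least the latent dimension for the corruption-0 layer to be invertible.
#' @param seed Seed for the random transforms and noise.
#' @return A `model_feature_set`: named list of layer matrices plus aligned
#'   `stimulus_ids` and a `provenance` tag (`"synthetic"`).
#' @export
generate_model_features <- function(ground_truth, layer_specs, seed = 1) {
  if (is.null(ground_truth$latent)) {
    abort("`ground_truth` must carry a shared latent (shared_signal = TRUE).")
  }
  lat <- ground_truth$latent
  layers <- vector("list", length(layer_specs))
  names(layers) <- names(layer_specs) %||% sprintf("layer_%d", seq_along(layer_specs))
  if (any(names(layers) == "")) names(layers) <- sprintf("layer_%d", seq_along(layer_specs))
  for (i in seq_along(layer_specs)) {
    spec <- layer_specs[[i]]
    cc <- spec$corruption
    if (is.null(cc) || cc < 0 || cc > 1) abort("corruption level must lie in [0, 1].")
    nf <- check_count(spec$n_features, "n_features")
    layers[[i]] <- with_seed(derive_seed(seed, 500 + i), {
      W <- matrix(rnorm(ncol(lat) * nf, sd = 1 / sqrt(ncol(lat))), ncol(lat), nf)
      noise <- matrix(rnorm(nrow(lat) * nf), nrow(lat), nf)
      sqrt(1 - cc) * (lat %*% W) + sqrt(cc) * noise
    })
  }
  model_feature_set(layers,
                    stimulus_ids = sprintf("stim_%03d", seq_len(nrow(lat))),
                    provenance = "synthetic")
}

#' Bundle per-layer model feature matrices
#'
#' @param layers Named list of `stimuli x features` numeric matrices, all with
#'   the same row count.
#' @param stimulus_ids Stimulus identifiers aligned with the rows.
#' @param provenance One of `"trained"`, `"untrained"`, `"synthetic"`.
#' @return A `model_feature_set` object.
#' @export
model_feature_set <- function(layers, stimulus_ids = NULL,
                              provenance = c("synthetic", "untrained", "trained")) {
  provenance <- match.arg(provenance)
  if (!length(layers)) abort("`layers` must be a nonempty list of matrices.")
  ns <- unique(vapply(layers, nrow, integer(1)))
  if (length(ns) != 1) abort("all layers must share the stimulus dimension.")
  if (is.null(stimulus_ids)) stimulus_ids <- sprintf("stim_%03d", seq_len(ns))
  if (length(stimulus_ids) != ns) abort("`stimulus_ids` length must match layer rows.")
  if (is.null(names(layers))) names(layers) <- sprintf("layer_%d", seq_along(layers))
  structure(list(layers = layers, stimulus_ids = as.character(stimulus_ids),
                 provenance = provenance),
            class = "model_feature_set")
}

#' @export
print.model_feature_set <- function(x, ...) {
  cat(sprintf("<model_feature_set> %d layers (%s), %d stimuli\n",
              length(x$layers), x$provenance, nrow(x$layers[[1]])))
  for (nm in names(x$layers)) {
    cat(sprintf("  %s: %d features\n", nm, ncol(x$layers[[nm]])))
  }
  invisible(x)
}
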