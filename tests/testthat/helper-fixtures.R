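# Shared fixture builders; everything is generated in code at test time.

small_cohort <- function(seed = 3, n_animals = 2, n_units = 15, n_stimuli = 40,
                         n_trials = 10, n_latent = 4, noise_sd = 1, ...) {
  generate_cohort(n_animals = n_animals, n_units = n_units,
                  n_stimuli = n_stimuli, n_trials = n_trials,
                  n_latent = n_latent, noise_sd = noise_sd, seed = seed, ...)
}

fast_half_plan <- function(n = 5, seed = 2) split_half_plan(n, seed = seed)
fast_split_plan <- function(n = 2, seed = 4) stimulus_split_plan(n_splits = n, seed = seed)

# noise sd that yields a target split-half consistency for unit signal sd 1
noise_sd_for_reliability <- function(r, n_trials) {
  sqrt((1 - r) / r * (n_trials / 2))
}

# recording whose unit groups sit at exact planted split-half reliabilities
# (true responses i.i.d. N(0,1) per unit, so no mixing-induced variance spread)
planted_reliability_recording <- function(reliabilities, n_units_per_group,
                                          n_stimuli = 2000, n_trials = 50,
                                          seed = 61) {
  groups <- lapply(seq_along(reliabilities), function(i) {
    rec <- generate_timebinned_recording(
      n_units = n_units_per_group, n_stimuli = n_stimuli, n_trials = n_trials,
      reliability_profile = reliabilities[i], seed = seed + i)
    interanimal:::recording_bin(rec, 1)
  })
  resp <- array(0, c(n_stimuli, n_trials, n_units_per_group * length(groups)))
  for (i in seq_along(groups)) {
    resp[, , (i - 1) * n_units_per_group + seq_len(n_units_per_group)] <-
      groups[[i]]$responses
  }
  population_recording(resp, "planted")
}
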