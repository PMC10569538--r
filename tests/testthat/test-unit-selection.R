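test_that("planted reliability mixture is filtered exactly at the threshold", {
  # split-half reliabilities 0.1 and 0.5 by construction;
  # SB-corrected ~0.18 vs ~0.67 around the 0.3 cutoff
  rec <- planted_reliability_recording(c(0.1, 0.5), n_units_per_group = 20,
                                       n_stimuli = 2000, seed = 61)
  rep_ <- calcium_unit_filter(rec, half_plan = split_half_plan(50, seed = 3))
  expect_equal(which(rep_$units$kept), 21:40)
  expect_equal(interanimal:::n_units(rep_$recording), 20L)
})

test_that("zero-noise units are all kept when no covariate is supplied", {
  sim <- small_cohort(seed = 62, noise_sd = 0, n_trials = 4)
  rep_ <- calcium_unit_filter(sim$recordings[[1]],
                              half_plan = split_half_plan(5, seed = 1))
  expect_true(all(rep_$units$kept))
})

test_that("a unit driven by the behavioral covariate is dropped", {
  sim <- generate_cohort(n_animals = 1, n_units = 10, n_stimuli = 30,
                         n_trials = 40, n_latent = 10, noise_sd = 0.1, seed = 63)
  rec <- sim$recordings[[1]]
  covar <- interanimal:::with_seed(8, matrix(rnorm(30 * 40), 30, 40))
  # make unit 1's response an exact linear function of the covariate
  rec$responses[, , 1] <- 2 * covar + 1
  rep_ <- calcium_unit_filter(rec, behavior_covariate = covar,
                              half_plan = split_half_plan(20, seed = 2),
                              n_permutations = 500, seed = 4)
  expect_false(rep_$units$kept_behavior[1])
  expect_true(mean(rep_$units$kept_behavior[-1]) > 0.8)
  expect_error(calcium_unit_filter(rec, behavior_covariate = covar[, 1:10]),
               "aligned")
})

test_that("window selection recovers a planted contiguous high-reliability run", {
  rec <- generate_timebinned_recording(n_units = 25, n_stimuli = 150, n_trials = 20,
                                       reliability_profile = c(0.05, 0.7, 0.7, 0.7, 0.05),
                                       seed = 64)
  sel <- neuropixels_window_select(rec, half_plan = split_half_plan(10, seed = 3))
  expect_equal(sel$window, 2:4)
  expect_equal(dim(sel$recording$responses), c(150L, 20L, 25L))
})

test_that("window selection handles the all-high, tie, and degenerate profiles", {
  rec_hi <- generate_timebinned_recording(n_units = 20, n_stimuli = 100, n_trials = 20,
                                          reliability_profile = rep(0.8, 4), seed = 65)
  expect_equal(neuropixels_window_select(rec_hi,
                                         half_plan = split_half_plan(5, seed = 1))$window,
               1:4)

  rec_lo <- generate_timebinned_recording(n_units = 20, n_stimuli = 100, n_trials = 20,
                                          reliability_profile = rep(0.02, 4), seed = 66)
  sel_lo <- neuropixels_window_select(rec_lo, half_plan = split_half_plan(5, seed = 1))
  expect_length(sel_lo$window, 0)
  expect_null(sel_lo$recording)

  # two equal-length runs: earlier wins (tested on the run finder directly)
  expect_equal(interanimal:::longest_true_run(c(TRUE, TRUE, FALSE, TRUE, TRUE)), 1:2)
})

test_that("window selection is invariant to unit ordering", {
  rec <- generate_timebinned_recording(n_units = 15, n_stimuli = 100, n_trials = 20,
                                       reliability_profile = c(0.1, 0.7, 0.7, 0.1),
                                       seed = 67)
  perm <- rev(seq_len(15))
  rec_perm <- population_recording(rec$responses[, , perm, , drop = FALSE],
                                   "perm", time_bin_ms = rec$time_bin_ms,
                                   stimulus_ids = rec$stimulus_ids)
  a <- neuropixels_window_select(rec, half_plan = split_half_plan(5, seed = 1))
  b <- neuropixels_window_select(rec_perm, half_plan = split_half_plan(5, seed = 1))
  expect_equal(a$window, b$window)
})

test_that("specimen percentile filter matches hand arithmetic", {
  counts <- tibble::tibble(specimen = c("a", "b", "c", "d"),
                           area = "VISp", n_units = c(4, 8, 15, 16))
  out <- specimen_percentile_filter(counts)
  # 75th percentile by linear interpolation: 15 + 0.25 * (16 - 15)
  expect_equal(out$threshold[1], 15.25)
  expect_equal(out$specimen[out$kept], "d")

  equal_counts <- tibble::tibble(specimen = letters[1:3], area = "VISl", n_units = 7)
  expect_true(all(specimen_percentile_filter(equal_counts)$kept))

  single <- tibble::tibble(specimen = "solo", area = "VISam", n_units = 3)
  expect_true(specimen_percentile_filter(single)$kept)
})

test_that("raising the reliability threshold never keeps more units", {
  sim <- generate_cohort(n_animals = 1, n_units = 30, n_stimuli = 60,
                         n_trials = 10, n_latent = 30, noise_sd = c(0.5, 6),
                         seed = 68)
  kept <- vapply(c(0.1, 0.3, 0.5, 0.7), function(th) {
    sum(calcium_unit_filter(sim$recordings[[1]], reliability_threshold = th,
                            half_plan = split_half_plan(10, seed = 2))$units$kept)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("filtering to reliable units raises the inter-animal ceiling estimate", {
  sim <- generate_cohort(n_animals = 2, n_units = 40, n_stimuli = 80,
                         n_trials = 20, n_latent = 5, noise_sd = c(0.5, 6), seed = 69)
  rep2 <- calcium_unit_filter(sim$recordings[[2]],
                              half_plan = split_half_plan(20, seed = 2))
  res_all <- pairwise_consistency(sim$recordings[[1]], sim$recordings[[2]],
                                  mapping_spec("ridge"),
                                  fast_half_plan(), fast_split_plan())
  res_kept <- pairwise_consistency(sim$recordings[[1]], rep2$recording,
                                   mapping_spec("ridge"),
                                   fast_half_plan(), fast_split_plan())
  expect_gte(res_kept$median, res_all$median - 0.02)
})
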