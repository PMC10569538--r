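test_that("split_trials yields disjoint equal halves, deterministic per seed", {
  sim <- small_cohort(seed = 31, n_trials = 2, noise_sd = 0)
  rec <- sim$recordings[[1]]
  h <- split_trials(rec, seed = 5)
  expect_equal(h$s1, h$s2, tolerance = 1e-12)  # zero noise: halves identical

  sim2 <- small_cohort(seed = 31, n_trials = 50)
  h1 <- split_trials(sim2$recordings[[1]], seed = 9)
  h2 <- split_trials(sim2$recordings[[1]], seed = 9)
  expect_identical(h1$s1, h2$s1)
  h3 <- split_trials(sim2$recordings[[1]], seed = 10)
  expect_false(identical(h1$s1, h3$s1))

  # odd trial count drops one trial and logs it
  rec_odd <- population_recording(sim2$recordings[[1]]$responses[, 1:5, , drop = FALSE],
                                  "odd")
  ho <- split_trials(rec_odd, seed = 1)
  expect_false(is.na(attr(ho, "dropped_trial")))
})

test_that("spearman_brown is exact and guards its domain", {
  expect_equal(spearman_brown(1), 1, tolerance = 1e-15)
  expect_equal(spearman_brown(0), 0, tolerance = 1e-15)
  expect_equal(spearman_brown(1 / 3), 0.5, tolerance = 1e-15)
  expect_equal(spearman_brown(c(0, 1 / 3, 1)), c(0, 0.5, 1), tolerance = 1e-15)
  expect_error(spearman_brown(-1), "greater than -1")
})

test_that("internal consistency matches closed forms at 1000 stimuli", {
  # unit signal variance 1, noise variance 1, 2 trials: r = 0.5, corrected 2/3
  sim <- generate_cohort(n_animals = 1, n_units = 40, n_stimuli = 1000,
                         n_trials = 2, n_latent = 40, noise_sd = 1, seed = 32)
  raw <- internal_consistency(sim$recordings[[1]], split_half_plan(20, seed = 2),
                              corrected = FALSE)
  corr <- internal_consistency(sim$recordings[[1]], split_half_plan(20, seed = 2),
                               corrected = TRUE)
  sig_var <- mean(apply(sim$ground_truth$true_responses[[1]], 2, var))
  expect_lt(abs(mean(raw$consistency) -
                analytic_split_half_consistency(sig_var, 1, 2)), 0.03)
  expect_lt(abs(mean(corr$consistency) - 2 / 3), 0.05)
})

test_that("the Gaussian split-half identity Corr(s1,s2) ~ Corr(t,s2)^2 holds", {
  sim <- generate_cohort(n_animals = 1, n_units = 5, n_stimuli = 10000,
                         n_trials = 10, n_latent = 5, noise_sd = 1, seed = 33)
  h <- split_trials(sim$recordings[[1]], seed = 4)
  t_true <- sim$ground_truth$true_responses[[1]]
  lhs <- interanimal:::corr_columns(h$s1, h$s2)
  rhs <- interanimal:::corr_columns(t_true, h$s2)^2
  expect_lt(max(abs(lhs - rhs)), 0.02)
})

test_that("noiseless identity-related populations score exactly 1", {
  sim <- generate_cohort(n_animals = 1, n_units = 10, n_stimuli = 40, n_trials = 4,
                         n_latent = 4, noise_sd = 0, seed = 34)
  rec <- sim$recordings[[1]]
  res <- pairwise_consistency(rec, rec, mapping_spec("identity"),
                              fast_half_plan(), fast_split_plan())
  expect_equal(res$median, 1, tolerance = 1e-10)
  expect_equal(res$per_unit$value, rep(1, 10), tolerance = 1e-10)
})

test_that("a linearly related noisy target recovers a corrected value near 1", {
  sim <- generate_cohort(n_animals = 2, n_units = 50, n_stimuli = 118,
                         n_trials = 50, n_latent = 10, noise_sd = 1, seed = 35)
  res <- pairwise_consistency(sim$recordings[[1]], sim$recordings[[2]],
                              mapping_spec("pls"),
                              split_half_plan(5, seed = 2),
                              stimulus_split_plan(n_splits = 2, seed = 3))
  expect_gt(res$median, 0.95)
  expect_lt(res$median, 1.05)
})

test_that("statistically independent populations score near 0", {
  sim <- generate_cohort(n_animals = 2, n_units = 30, n_stimuli = 118,
                         n_trials = 20, n_latent = 10, noise_sd = 1,
                         shared_signal = FALSE, seed = 36)
  res <- pairwise_consistency(sim$recordings[[1]], sim$recordings[[2]],
                              mapping_spec("ridge"),
                              split_half_plan(5, seed = 2),
                              stimulus_split_plan(n_splits = 2, seed = 3))
  expect_lt(abs(res$median), 0.06)
})

test_that("pooled consistency reduces to pairwise for two animals", {
  sim <- small_cohort(seed = 37)
  pooled <- pooled_consistency(sim$recordings, mapping_spec("ridge"),
                               fast_half_plan(), fast_split_plan())
  direct <- pairwise_consistency(sim$recordings[[1]], sim$recordings[[2]],
                                 mapping_spec("ridge"),
                                 fast_half_plan(), fast_split_plan())
  expect_equal(pooled[[2]]$per_unit$value, direct$per_unit$value, tolerance = 1e-12)
})

test_that("pooling more identical-signal animals does not hurt the ceiling", {
  sim <- generate_cohort(n_animals = 3, n_units = 20, n_stimuli = 80,
                         n_trials = 20, n_latent = 5, noise_sd = 1.5, seed = 38)
  pooled <- aggregate_units(pooled_consistency(sim$recordings, mapping_spec("ridge"),
                                               fast_half_plan(), fast_split_plan()))
  pairwise <- aggregate_units(list(
    pairwise_consistency(sim$recordings[[1]], sim$recordings[[3]], mapping_spec("ridge"),
                         fast_half_plan(), fast_split_plan()),
    pairwise_consistency(sim$recordings[[2]], sim$recordings[[1]], mapping_spec("ridge"),
                         fast_half_plan(), fast_split_plan()),
    pairwise_consistency(sim$recordings[[3]], sim$recordings[[2]], mapping_spec("ridge"),
                         fast_half_plan(), fast_split_plan())))
  expect_gte(pooled$median, pairwise$median - 0.02)
})

test_that("the corrected value dominates the raw numerator when reliabilities are below 1", {
  sim <- generate_cohort(n_animals = 2, n_units = 25, n_stimuli = 100,
                         n_trials = 10, n_latent = 5, noise_sd = 2, seed = 39)
  res <- pairwise_consistency(sim$recordings[[1]], sim$recordings[[2]],
                              mapping_spec("ridge"),
                              fast_half_plan(), fast_split_plan())
  d <- res$diagnostics
  expect_true(all(d$mean_map_reliability < 1 & d$mean_target_reliability > 0))
  expect_gt(res$median, mean(d$mean_numerator))
})

test_that("the raw numerator is non-increasing in trial noise", {
  meds <- vapply(c(0.5, 2.5), function(ns) {
    sim <- generate_cohort(n_animals = 2, n_units = 20, n_stimuli = 80,
                           n_trials = 10, n_latent = 5, noise_sd = ns, seed = 40)
    res <- pairwise_consistency(sim$recordings[[1]], sim$recordings[[2]],
                                mapping_spec("ridge"),
                                fast_half_plan(), fast_split_plan())
    mean(res$diagnostics$mean_numerator)
  }, numeric(1))
  expect_gt(meds[1], meds[2])
})

test_that("nonlinear inter-animal relations lower the linear-map consistency", {
  med_of <- function(nl) {
    sim <- generate_cohort(n_animals = 2, n_units = 30, n_stimuli = 100,
                           n_trials = 20, n_latent = 5, noise_sd = 0.7,
                           nonlinearity = nl, seed = 41)
    pairwise_consistency(sim$recordings[[1]], sim$recordings[[2]],
                         mapping_spec("ridge"),
                         fast_half_plan(), fast_split_plan())$median
  }
  expect_gt(med_of("none"), med_of("rectify") - 0.02)
})

test_that("aggregation concatenates units, is order-invariant, and flags empties", {
  mk <- function(vals, id) {
    consistency_result(tibble::tibble(animal_id = id, unit = seq_along(vals),
                                      value = vals, n_valid = 5L, n_total = 5L,
                                      dropped = FALSE))
  }
  a <- mk(c(0.2, 0.4), "a"); b <- mk(c(0.6, 0.8), "b")
  agg <- aggregate_units(list(a, b))
  expect_equal(agg$median, 0.5)
  agg_rev <- aggregate_units(list(b, a))
  expect_equal(agg$median, agg_rev$median)
  expect_equal(sort(agg$per_unit$value), sort(agg_rev$per_unit$value))
  single <- aggregate_units(a)
  expect_equal(single$median, 0.3)
  dropped <- mk(c(0.1), "c"); dropped$per_unit$dropped <- TRUE
  expect_error(aggregate_units(list(dropped)), "excluded")
})

test_that("tidy/glance/autoplot methods expose the result tables", {
  sim <- small_cohort(seed = 42)
  res <- pairwise_consistency(sim$recordings[[1]], sim$recordings[[2]],
                              mapping_spec("ridge"), fast_half_plan(), fast_split_plan())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("animal_id", "unit", "value") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$median, res$median)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
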