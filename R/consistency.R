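#' Bootstrap plan for split-half trial resampling
#'
#' @param n_bootstraps Number of random disjoint trial-half resamples
#'   (default 100).
#' @param seed Seed for the half assignments.
#' @return A `split_half_plan`.
#' @export
split_half_plan <- function(n_bootstraps = 100, seed = 1) {
  n_bootstraps <- check_count(n_bootstraps, "n_bootstraps")
  structure(list(n_bootstraps = n_bootstraps, seed = seed),
            class = "split_half_plan")
}

#' Train/test stimulus split plan
#'
#' Default mirrors a 50/50 split of the stimulus set across ten random
#' train/test partitions.
#'
#' @param train_fraction Fraction of stimuli used for training (in (0, 1)).
#' @param n_splits Number of random splits (default 10).
#' @param seed Seed for the splits.
#' @return A `stimulus_split_plan`.
#' @export
stimulus_split_plan <- function(train_fraction = 0.5, n_splits = 10, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  n_splits <- check_count(n_splits, "n_splits")
  structure(list(train_fraction = train_fraction, n_splits = n_splits, seed = seed),
            class = "stimulus_split_plan")
}

#' Split trials into two disjoint half-averages
#'
#' Randomly assigns trials to two disjoint halves of equal size and averages
#' each half, giving two independent `stimuli x units` estimates of the same
#' underlying response. Odd trial counts drop one randomly chosen trial
#' (recorded in attribute `"dropped_trial"`).
#'
#' @param recording A [population_recording()] with at least 2 trials.
#' @param seed Seed controlling the random assignment.
#' @return List with matrices `s1` and `s2`.
#' @export
split_trials <- function(recording, seed = 1) {
  nt <- n_trials(recording)
  if (nt < 2) abort("at least 2 trials are required to split.")
  with_seed(seed, {
    perm <- sample.int(nt)
    half <- nt %/% 2
    dropped <- if (nt %% 2 == 1) perm[nt] else NA_integer_
    s1 <- trial_average(recording, perm[seq_len(half)])
    s2 <- trial_average(recording, perm[half + seq_len(half)])
    out <- list(s1 = s1, s2 = s2)
    attr(out, "dropped_trial") <- dropped
    out
  })
}

#' Spearman-Brown correction
#'
#' Adjusts a split-half correlation to the full-data equivalent:
#' `2 r / (1 + r)`. Under additive Gaussian noise this maps the reliability
#' of two half-trial averages onto the reliability of full-trial averages.
#'
#' @param r Correlation value(s) in `(-1, 1]`.
#' @return Corrected correlation(s).
#' @export
spearman_brown <- function(r) {
  if (any(r <= -1, na.rm = TRUE)) abort("`r` must be greater than -1.")
  2 * r / (1 + r)
}

#' Per-unit split-half internal consistency
#'
#' Correlates the two half-trial averages across stimuli for each unit,
#' averaged over bootstrap resamples of the half assignment, optionally with
#' Spearman-Brown correction (applied per bootstrap, before averaging).
#' Bootstraps in which a unit is constant across stimuli are excluded for
#' that unit and counted.
#'
#' @param recording A [population_recording()] (>= 2 trials, >= 3 stimuli).
#' @param plan A [split_half_plan()].
#' @param corrected Apply Spearman-Brown correction (default `TRUE`).
#' @return Tibble with `unit`, `consistency`, `n_used` (valid bootstraps).
#' @export
internal_consistency <- function(recording, plan = split_half_plan(),
                                 corrected = TRUE) {
  if (n_stimuli(recording) < 3) abort("at least 3 stimuli are required.")
  p <- n_units(recording)
  acc <- matrix(NA_real_, plan$n_bootstraps, p)
  for (b in seq_len(plan$n_bootstraps)) {
    halves <- split_trials(recording, seed = derive_seed(plan$seed, b))
    r <- corr_columns(halves$s1, halves$s2)
    if (corrected) r <- ifelse(!is.na(r) & r > -1, spearman_brown(pmin(r, 1)), NA_real_)
    acc[b, ] <- r
  }
  tibble(unit = seq_len(p),
         consistency = colMeans(acc, na.rm = TRUE),
         n_used = colSums(!is.na(acc)))
}

# --- shared engine for the noise-corrected ratio -----------------------------

# source_halves(b) must return list(x1, x2): the two source estimates for
# bootstrap b (identical deterministic features in model mode). The corrected
# ratio per target unit is num / denom with
#   num   = Corr(M(x1)_test, s2B_test)
#   denom = sqrt(SB(Corr(M(x1)_test, M(x2)_test)) * SB(Corr(s1B_test, s2B_test)))
# (or sqrt on the mapping term only), averaged over bootstraps and splits.
corrected_consistency_engine <- function(source_halves, target, spec,
                                         half_plan, split_plan,
                                         denominator_form = "sqrt_product",
                                         label = "") {
  ns <- n_stimuli(target)
  p <- n_units(target)
  sum_ratio <- numeric(p); n_valid <- integer(p); n_total <- 0L
  diag_rows <- vector("list", split_plan$n_splits * half_plan$n_bootstraps)
  di <- 0L

  for (s in seq_len(split_plan$n_splits)) {
    train <- with_seed(derive_seed(split_plan$seed, 3000 + s),
                       sort(sample.int(ns, round(split_plan$train_fraction * ns))))
    test <- setdiff(seq_len(ns), train)
    if (length(train) < 2 || length(test) < 3) {
      abort("stimulus split leaves too few train or test stimuli.")
    }
    for (b in seq_len(half_plan$n_bootstraps)) {
      bseed <- derive_seed(half_plan$seed, s * 1000 + b)
      th <- split_trials(target, seed = bseed)
      sh <- source_halves(derive_seed(bseed, 17))

      m1 <- fit_map(sh$x1[train, , drop = FALSE], th$s1[train, , drop = FALSE], spec)
      m2 <- fit_map(sh$x2[train, , drop = FALSE], th$s2[train, , drop = FALSE], spec)
      pred1 <- predict(m1, sh$x1[test, , drop = FALSE])
      pred2 <- predict(m2, sh$x2[test, , drop = FALSE])

      num <- corr_columns(pred1, th$s2[test, , drop = FALSE])
      map_rel <- corr_columns(pred1, pred2)
      tgt_rel <- corr_columns(th$s1[test, , drop = FALSE], th$s2[test, , drop = FALSE])

      ok <- !is.na(num) & !is.na(map_rel) & !is.na(tgt_rel) &
        map_rel > 0 & tgt_rel > 0
      sb_map <- spearman_brown(pmin(ifelse(ok, map_rel, NA_real_), 1))
      sb_tgt <- spearman_brown(pmin(ifelse(ok, tgt_rel, NA_real_), 1))
      denom <- if (denominator_form == "sqrt_product") {
        sqrt(sb_map * sb_tgt)
      } else {
        sqrt(sb_map) * sb_tgt
      }
      ratio <- ifelse(ok, num / denom, NA_real_)

      sum_ratio <- sum_ratio + ifelse(ok, ratio, 0)
      n_valid <- n_valid + ok
      n_total <- n_total + 1L
      di <- di + 1L
      diag_rows[[di]] <- tibble(
        split = s, bootstrap = b,
        mean_numerator = mean(num[ok]),
        mean_map_reliability = mean(map_rel[ok]),
        mean_target_reliability = mean(tgt_rel[ok]),
        n_excluded = sum(!ok))
    }
  }

  value <- ifelse(n_valid > 0, sum_ratio / n_valid, NA_real_)
  dropped <- n_valid < n_total / 2  # > 50% excluded bootstraps drops the unit
  per_unit <- tibble(animal_id = target$animal_id, unit = seq_len(p),
                     value = value, n_valid = n_valid, n_total = n_total,
                     dropped = dropped | is.na(value))
  consistency_result(per_unit, diagnostics = bind_rows(diag_rows),
                     metadata = list(label = label, mapping = spec$kind,
                                     denominator_form = denominator_form,
                                     n_bootstraps = half_plan$n_bootstraps,
                                     n_splits = split_plan$n_splits))
}

#' Noise-corrected inter-animal consistency for one animal pair
#'
#' Estimates how well a mapped version of the source animal's responses
#' predicts the target animal's true responses, correcting the raw test-set
#' correlation by the square root of the product of the Spearman-Brown
#' corrected mapping reliability (agreement of predictions trained on the two
#' source/target half-splits) and the target's internal consistency. For each
#' bootstrap and stimulus split the mapping is fit twice, once per trial
#' half; the corrected ratio is averaged per target unit over bootstraps and
#' splits, and the median and s.e.m. are taken across units.
#'
#' Unit-bootstraps with a non-positive or undefined denominator term are
#' excluded from that unit's average; a unit with more than half of its
#' bootstraps excluded is dropped and reported.
#'
#' @param source,target [population_recording()]s sharing a stimulus set.
#' @param spec A [mapping_spec()].
#' @param half_plan A [split_half_plan()].
#' @param split_plan A [stimulus_split_plan()].
#' @param denominator_form `"sqrt_product"` (default: the radical covers the
#'   product of both corrected terms) or `"sqrt_mapping_only"` (radical on
#'   the mapping-reliability term alone), for sensitivity checks.
#' @return A [consistency_result()] for the target animal's units.
#' @export
pairwise_consistency <- function(source, target, spec = mapping_spec(),
                                 half_plan = split_half_plan(),
                                 split_plan = stimulus_split_plan(),
                                 denominator_form = c("sqrt_product", "sqrt_mapping_only")) {
  denominator_form <- match.arg(denominator_form)
  if (!identical(source$stimulus_ids, target$stimulus_ids)) {
    abort("`source` and `target` must share the same stimulus set.")
  }
  corrected_consistency_engine(
    source_halves = function(seed) {
      h <- split_trials(source, seed = seed)
      list(x1 = h$s1, x2 = h$s2)
    },
    target = target, spec = spec, half_plan = half_plan,
    split_plan = split_plan, denominator_form = denominator_form,
    label = sprintf("%s -> %s (%s)", source$animal_id, target$animal_id, spec$kind))
}

#' Pooled-source inter-animal consistency across a cohort
#'
#' Holds out each animal in turn as the target and maps to it from the
#' pseudo-population formed by concatenating the units of all remaining
#' animals, then applies the pairwise noise-corrected estimator. Pooling
#' gives the source more units than any single animal and tightens the
#' ceiling estimate when per-animal unit counts are small.
#'
#' @param cohort List of at least two [population_recording()]s sharing a
#'   stimulus set.
#' @inheritParams pairwise_consistency
#' @return List of [consistency_result()], one per held-out target; pool
#'   them with [aggregate_units()].
#' @export
pooled_consistency <- function(cohort, spec = mapping_spec(),
                               half_plan = split_half_plan(),
                               split_plan = stimulus_split_plan(),
                               denominator_form = c("sqrt_product", "sqrt_mapping_only")) {
  denominator_form <- match.arg(denominator_form)
  if (length(cohort) < 2) abort("`cohort` must contain at least 2 animals.")
  lapply(seq_along(cohort), function(i) {
    source <- if (length(cohort) == 2) cohort[[setdiff(1:2, i)]] else {
      pool_recordings(cohort[-i])
    }
    pairwise_consistency(source, cohort[[i]], spec = spec,
                         half_plan = half_plan, split_plan = split_plan,
                         denominator_form = denominator_form)
  })
}
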