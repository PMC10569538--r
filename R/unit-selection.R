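#' Reliability and behavioral-modulation unit filter
#'
#' Implements the conditioning applied to imaging-style recordings: keep
#' units whose Spearman-Brown corrected split-half consistency (averaged over
#' bootstraps) reaches `reliability_threshold`, and whose peak response to
#' their preferred stimulus is not significantly modulated by a behavioral
#' covariate such as running speed.
#'
#' The modulation test is a two-sided permutation test (default 1000
#' permutations) on the Spearman correlation between the covariate and the
#' unit's single-trial responses to its preferred stimulus (the stimulus with
#' maximal trial-mean response; ties broken by the lowest stimulus index).
#' The source data this procedure emulates does not name a test, so this
#' choice is an explicit stand-in; any unit with `p <= p_threshold` is
#' dropped.
#'
#' @param recording A [population_recording()].
#' @param behavior_covariate Optional `stimuli x trials` matrix of a
#'   per-presentation scalar (e.g. running speed), aligned with
#'   `recording$responses`; `NULL` skips the modulation criterion.
#' @param reliability_threshold Minimum corrected split-half consistency
#'   (default 0.3).
#' @param p_threshold Units with modulation `p <= p_threshold` are dropped
#'   (default 0.05).
#' @param half_plan A [split_half_plan()] (default 100 bootstraps).
#' @param n_permutations Permutations for the modulation test.
#' @param seed Seed for the permutation test.
#' @return A `selection_report`: tibble `units` with per-unit `reliability`,
#'   `p_value`, `kept_reliability`, `kept_behavior`, `kept`; plus the kept
#'   recording in `$recording` and the thresholds echoed in `$thresholds`.
#' @export
calcium_unit_filter <- function(recording, behavior_covariate = NULL,
                                reliability_threshold = 0.3,
                                p_threshold = 0.05,
                                half_plan = split_half_plan(),
                                n_permutations = 1000, seed = 1) {
  ic <- internal_consistency(recording, plan = half_plan, corrected = TRUE)
  p <- n_units(recording)
  pvals <- rep(NA_real_, p)
  if (!is.null(behavior_covariate)) {
    if (!all(dim(behavior_covariate) == dim(recording$responses)[1:2])) {
      abort("`behavior_covariate` must be a stimuli x trials matrix aligned to the recording.")
    }
    means <- trial_average(recording)
    for (u in seq_len(p)) {
      pref <- which.max(means[, u])  # preferred image; ties -> lowest index
      y <- recording$responses[pref, , u]
      x <- behavior_covariate[pref, ]
      pvals[u] <- permutation_p_spearman(x, y, n_permutations,
                                         seed = derive_seed(seed, u))
    }
  }
  kept_rel <- ic$consistency >= reliability_threshold & !is.na(ic$consistency)
  kept_beh <- if (is.null(behavior_covariate)) rep(TRUE, p) else pvals > p_threshold
  kept <- kept_rel & kept_beh
  units <- tibble(unit = seq_len(p), reliability = ic$consistency,
                  p_value = pvals, kept_reliability = kept_rel,
                  kept_behavior = kept_beh, kept = kept)
  kept_rec <- if (any(kept)) {
    population_recording(recording$responses[, , kept, drop = FALSE],
                         recording$animal_id, recording$area,
                         stimulus_ids = recording$stimulus_ids)
  } else NULL
  structure(list(units = units, recording = kept_rec,
                 thresholds = list(reliability = reliability_threshold,
                                   p = p_threshold)),
            class = "selection_report")
}

permutation_p_spearman <- function(x, y, n_permutations, seed) {
  if (sd(x) == 0 || sd(y) == 0) return(1)
  obs <- cor(x, y, method = "spearman")
  with_seed(seed, {
    perms <- vapply(seq_len(n_permutations), function(i) {
      cor(sample(x), y, method = "spearman")
    }, numeric(1))
    # two-sided permutation p with the +1 convention
    (1 + sum(abs(perms) >= abs(obs))) / (n_permutations + 1)
  })
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d / %d units kept\n",
              sum(x$units$kept), nrow(x$units)))
  invisible(x)
}

#' Temporal window selection for time-binned recordings
#'
#' Finds the largest contiguous run of time bins in which the population
#' median split-half consistency (Spearman-Brown corrected, averaged over
#' bootstraps) reaches the threshold, then averages responses over that
#' window. Ties between equal-length runs are broken by the earlier window.
#' This mirrors the treatment of binned electrophysiology responses, where
#' different specimens become reliable over different latency ranges.
#'
#' @param recording A [population_recording()] with a time axis.
#' @param reliability_threshold Median consistency required (default 0.3).
#' @param max_ms Only bins up to this latency are considered (default 250).
#' @param half_plan A [split_half_plan()] used per bin.
#' @return List with `window` (integer bin indices; empty when no bin
#'   qualifies), `per_bin` (tibble `bin`, `median_consistency`, `qualifies`)
#'   and `recording` (window-averaged 3-D recording, or `NULL` when the
#'   window is empty).
#' @export
neuropixels_window_select <- function(recording, reliability_threshold = 0.3,
                                      max_ms = 250,
                                      half_plan = split_half_plan()) {
  nb <- n_bins(recording)
  if (is.null(nb)) abort("`recording` must carry a time axis.")
  use_bins <- seq_len(min(nb, max_ms %/% recording$time_bin_ms))
  med <- vapply(use_bins, function(k) {
    ic <- internal_consistency(recording_bin(recording, k), plan = half_plan)
    median(ic$consistency, na.rm = TRUE)
  }, numeric(1))
  qualifies <- med >= reliability_threshold
  window <- longest_true_run(qualifies)
  per_bin <- tibble(bin = use_bins, median_consistency = med,
                    qualifies = qualifies)
  averaged <- NULL
  if (length(window)) {
    resp <- recording$responses[, , , window, drop = FALSE]
    resp <- apply(resp, 1:3, mean)
    dim(resp) <- dim(recording$responses)[1:3]
    averaged <- population_recording(resp, recording$animal_id, recording$area,
                                     stimulus_ids = recording$stimulus_ids)
  }
  list(window = window, per_bin = per_bin, recording = averaged)
}

# Indices of the longest contiguous TRUE run; earliest run wins ties.
longest_true_run <- function(flags) {
  if (!any(flags)) return(integer(0))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  seq(starts[best], ends[best])
}

#' Keep specimens with enough units per area
#'
#' Retains, within each area, the specimens whose unit count is at least the
#' 75th percentile (linear interpolation between order statistics) of that
#' area's counts — ensuring enough internally consistent units per specimen
#' for ceiling estimation.
#'
#' @param unit_counts Tibble/data frame with columns `specimen`, `area`,
#'   `n_units`.
#' @param percentile Percentile cutoff in \[0, 100\] (default 75).
#' @return Tibble with `specimen`, `area`, `n_units`, `threshold`, `kept`.
#' @export
specimen_percentile_filter <- function(unit_counts, percentile = 75) {
  unit_counts <- as_tibble(unit_counts)
  if (!all(c("specimen", "area", "n_units") %in% names(unit_counts))) {
    abort("`unit_counts` needs columns specimen, area, n_units.")
  }
  if (!nrow(unit_counts)) abort("`unit_counts` is empty.")
  unit_counts |>
    group_by(.data$area) |>
    mutate(threshold = unname(quantile(.data$n_units, percentile / 100, type = 7)),
           kept = .data$n_units >= .data$threshold) |>
    ungroup()
}
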