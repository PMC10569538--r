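#' Trial-structured population recording
#'
#' Container for one animal's responses to a fixed stimulus set, stored as a
#' `stimuli x trials x units` numeric array (or `stimuli x trials x units x
#' time_bins` when a time axis is present). This is the unit of every
#' consistency computation in the package.
#'
#' @param responses Numeric array, `stimuli x trials x units`, optionally with
#'   a fourth time-bin dimension. Must contain no missing values.
#' @param animal_id Character scalar identifying the animal/specimen.
#' @param area Character scalar, the cortical area label (e.g. `"VISp"`).
#' @param time_bin_ms Optional positive integer, bin width in milliseconds
#'   when `responses` has a time axis.
#' @param stimulus_ids Character vector of unique stimulus identifiers, one
#'   per stimulus; defaults to `"stim_001"` style labels.
#'
#' @return An object of class `population_recording`.
#' @export
population_recording <- function(responses, animal_id, area = "VISp",
                                 time_bin_ms = NULL, stimulus_ids = NULL) {
  if (!is.array(responses) || !(length(dim(responses)) %in% c(3L, 4L))) {
    abort("`responses` must be a 3-D (or 4-D time-binned) numeric array.")
  }
  if (anyNA(responses)) abort("`responses` contains undefined values.")
  d <- dim(responses)
  if (d[1] < 2) abort("at least 2 stimuli are required.")
  if (d[2] < 2) abort("at least 2 trials are required for any consistency computation.")
  if (length(dim(responses)) == 4L && is.null(time_bin_ms)) {
    abort("`time_bin_ms` must be given when `responses` has a time axis.")
  }
  if (!is.null(time_bin_ms)) {
    time_bin_ms <- check_count(time_bin_ms, "time_bin_ms", min = 1)
  }
  if (is.null(stimulus_ids)) {
    stimulus_ids <- sprintf("stim_%03d", seq_len(d[1]))
  }
  if (length(stimulus_ids) != d[1]) abort("`stimulus_ids` length must match stimuli.")
  if (anyDuplicated(stimulus_ids)) abort("`stimulus_ids` must be unique.")
  structure(
    list(responses = responses,
         animal_id = as.character(animal_id),
         area = as.character(area),
         time_bin_ms = time_bin_ms,
         stimulus_ids = as.character(stimulus_ids)),
    class = "population_recording"
  )
}

#' @export
print.population_recording <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("<population_recording> animal %s, area %s\n", x$animal_id, x$area))
  cat(sprintf("  %d stimuli x %d trials x %d units", d[1], d[2], d[3]))
  if (length(d) == 4L) cat(sprintf(" x %d bins (%d ms)", d[4], x$time_bin_ms))
  cat("\n")
  invisible(x)
}

n_stimuli <- function(x) dim(x$responses)[1]
n_trials <- function(x) dim(x$responses)[2]
n_units <- function(x) dim(x$responses)[3]
n_bins <- function(x) if (length(dim(x$responses)) == 4L) dim(x$responses)[4] else NULL

# Trial-averaged responses (stimuli x units), optionally over a trial subset.
trial_average <- function(recording, trials = NULL) {
  r <- recording$responses
  if (is.null(trials)) trials <- seq_len(dim(r)[2])
  m <- r[, trials, , drop = FALSE]
  out <- colMeans(aperm(m, c(2, 1, 3)))  # mean over trials, C-level
  dim(out) <- c(dim(r)[1], dim(r)[3])
  out
}

# Single time bin of a 4-D recording as a plain 3-D recording.
recording_bin <- function(recording, bin) {
  stopifnot(length(dim(recording$responses)) == 4L)
  resp <- recording$responses[, , , bin, drop = FALSE]
  dim(resp) <- dim(recording$responses)[1:3]
  population_recording(resp, recording$animal_id, recording$area,
                       stimulus_ids = recording$stimulus_ids)
}

# Concatenate units of several recordings into a pooled pseudo-population.
pool_recordings <- function(recordings) {
  stopifnot(length(recordings) >= 1)
  ids <- recordings[[1]]$stimulus_ids
  for (r in recordings) {
    if (!identical(r$stimulus_ids, ids)) abort("recordings must share a stimulus set.")
  }
  nt <- min(vapply(recordings, n_trials, integer(1)))
  arrs <- lapply(recordings, function(r) r$responses[, seq_len(nt), , drop = FALSE])
  resp <- array(0, c(dim(arrs[[1]])[1], nt, sum(vapply(arrs, function(a) dim(a)[3], integer(1)))))
  at <- 0L
  for (a in arrs) {
    resp[, , at + seq_len(dim(a)[3])] <- a
    at <- at + dim(a)[3]
  }
  population_recording(resp, animal_id = "pooled",
                       area = recordings[[1]]$area, stimulus_ids = ids)
}
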