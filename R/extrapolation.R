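#' Log-linear extrapolation of consistency over population size
#'
#' Fits `f(n) = a * log10(n) + b` by least squares to consistency values
#' measured at different sample sizes (or sample-size factors), giving an
#' extrapolation of how the inter-animal ceiling grows as more units (or
#' stimuli) are recorded. Predictions are clipped at 1 on report, with a flag
#' when clipping occurs.
#'
#' @param sample_sizes Positive sample sizes (>= 2 distinct values).
#' @param consistencies Consistency values, one per sample size.
#' @return A `loglinear_fit` with elements `a`, `b`, `fitted`, `residuals`
#'   and a `predict(n)` function returning a tibble with `n`, `prediction`,
#'   `clipped`.
#' @export
fit_loglinear_extrapolation <- function(sample_sizes, consistencies) {
  if (length(sample_sizes) != length(consistencies)) {
    abort("`sample_sizes` and `consistencies` must have equal length.")
  }
  if (any(sample_sizes <= 0)) abort("`sample_sizes` must be positive.")
  if (length(unique(sample_sizes)) < 2) {
    abort("at least 2 distinct sample sizes are required.")
  }
  x <- log10(sample_sizes)
  fit <- lm(consistencies ~ x)
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  predict_fn <- function(n) {
    if (any(n <= 0)) abort("`n` must be positive.")
    raw <- a * log10(n) + b
    tibble(n = n, prediction = pmin(raw, 1), clipped = raw > 1)
  }
  structure(list(a = a, b = b,
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals),
                 data = tibble(n = sample_sizes, consistency = consistencies),
                 predict = predict_fn),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf("<loglinear_fit> f(n) = %.4f log10(n) + %.4f\n", x$a, x$b))
  invisible(x)
}

#' @export
tidy.loglinear_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.loglinear_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, rss = sum(x$residuals^2), n_points = nrow(x$data))
}

#' @export
autoplot.loglinear_fit <- function(object, ...) {
  grid <- 10^seq(log10(min(object$data$n)), log10(max(object$data$n) * 2),
                 length.out = 100)
  pr <- object$predict(grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n, y = .data$consistency)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pr, ggplot2::aes(x = .data$n, y = .data$prediction),
                       colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sample size", y = "consistency") +
    ggplot2::theme_minimal()
}

#' Consistency as a function of subsampled unit count
#'
#' Subsamples each animal's units at the requested fractions and recomputes
#' the pooled-source noise-corrected consistency at each size, producing the
#' points a log-linear extrapolation is fit to.
#'
#' @param cohort List of [population_recording()]s.
#' @param fractions Unit fractions in (0, 1] to evaluate.
#' @param spec,half_plan,split_plan Passed to [pooled_consistency()].
#' @param seed Seed for the unit subsamples.
#' @return Tibble with `fraction`, `n_units` (pooled target units kept) and
#'   `median` consistency.
#' @export
subsampled_consistency <- function(cohort, fractions = c(0.25, 0.5, 1),
                                   spec = mapping_spec(),
                                   half_plan = split_half_plan(),
                                   split_plan = stimulus_split_plan(),
                                   seed = 1) {
  if (any(fractions <= 0 | fractions > 1)) abort("`fractions` must lie in (0, 1].")
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    sub <- lapply(seq_along(cohort), function(j) {
      rec <- cohort[[j]]
      k <- max(2L, round(f * n_units(rec)))
      keep <- with_seed(derive_seed(seed, i * 100 + j),
                        sort(sample.int(n_units(rec), k)))
      population_recording(rec$responses[, , keep, drop = FALSE],
                           rec$animal_id, rec$area,
                           stimulus_ids = rec$stimulus_ids)
    })
    agg <- aggregate_units(pooled_consistency(sub, spec = spec,
                                              half_plan = half_plan,
                                              split_plan = split_plan))
    tibble(fraction = f, n_units = agg$n_units, median = agg$median)
  })
  bind_rows(rows)
}
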