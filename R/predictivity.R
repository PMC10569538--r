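#' Noise-corrected neural predictivity of model feature layers
#'
#' Scores each model layer against each target animal with the same
#' noise-corrected regression metric used for inter-animal consistency, the
#' source animal replaced by the layer's deterministic features: per
#' bootstrap and stimulus split the mapping is fit from the (trial-free)
#' features to each of the target's two half-trial averages, and the raw
#' test-set correlation is corrected by
#' `sqrt(SB(Corr(pred1, pred2)) * SB(Corr(s1B, s2B)))`. Per-unit averaged
#' values are concatenated across target animals; the best layer is the one
#' with the highest median.
#'
#' @param features A [model_feature_set()] whose `stimulus_ids` match the
#'   recordings'.
#' @param targets A [population_recording()] or list of them.
#' @inheritParams pairwise_consistency
#' @return A `predictivity_result`: `by_layer` tibble (`layer`, `median`,
#'   `sem`, `n_units`, `n_dropped`), `best_layer`, and the per-layer lists of
#'   [consistency_result()]s in `$results`.
#' @export
model_neural_predictivity <- function(features, targets, spec = mapping_spec(),
                                      half_plan = split_half_plan(),
                                      split_plan = stimulus_split_plan(),
                                      denominator_form = c("sqrt_product", "sqrt_mapping_only")) {
  denominator_form <- match.arg(denominator_form)
  if (inherits(targets, "population_recording")) targets <- list(targets)
  for (tg in targets) {
    if (!identical(features$stimulus_ids, tg$stimulus_ids)) {
      abort("feature and recording stimulus sets must be aligned.")
    }
  }
  results <- lapply(names(features$layers), function(nm) {
    feat <- features$layers[[nm]]
    lapply(targets, function(tg) {
      corrected_consistency_engine(
        source_halves = function(seed) list(x1 = feat, x2 = feat),
        target = tg, spec = spec, half_plan = half_plan,
        split_plan = split_plan, denominator_form = denominator_form,
        label = sprintf("%s -> %s (%s)", nm, tg$animal_id, spec$kind))
    })
  })
  names(results) <- names(features$layers)
  by_layer <- bind_rows(lapply(names(results), function(nm) {
    agg <- aggregate_units(results[[nm]])
    tibble(layer = nm, median = agg$median, sem = agg$sem,
           n_units = agg$n_units, n_dropped = agg$n_dropped)
  }))
  best <- by_layer$layer[which.max(by_layer$median)]
  structure(list(by_layer = by_layer, best_layer = best, results = results,
                 metadata = list(mapping = spec$kind,
                                 n_bootstraps = half_plan$n_bootstraps,
                                 n_splits = split_plan$n_splits)),
            class = "predictivity_result")
}

#' @export
print.predictivity_result <- function(x, ...) {
  cat(sprintf("<predictivity_result> best layer: %s\n", x$best_layer))
  print(x$by_layer)
  invisible(x)
}

#' @export
tidy.predictivity_result <- function(x, ...) x$by_layer

#' @export
glance.predictivity_result <- function(x, ...) {
  best <- x$by_layer[x$by_layer$layer == x$best_layer, ]
  tibble(best_layer = x$best_layer, best_median = best$median,
         best_sem = best$sem, n_layers = nrow(x$by_layer))
}

#' Per-layer medians of a predictivity result
#'
#' @param object A `predictivity_result`.
#' @param ... Unused.
#' @return A ggplot object with median +/- s.e.m. per layer.
#' @export
autoplot.predictivity_result <- function(object, ...) {
  df <- object$by_layer
  df$layer <- factor(df$layer, levels = df$layer)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$median)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$median - .data$sem,
                                        ymax = .data$median + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "noise-corrected predictivity (median)") +
    ggplot2::theme_minimal()
}
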