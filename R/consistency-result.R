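#' Construct a consistency result
#'
#' Holds per-target-unit noise-corrected values (each already averaged over
#' bootstraps and train/test splits — one value per unit), per-bootstrap
#' numerator/denominator diagnostics, an excluded-unit log, and the
#' median +/- s.e.m. summary. Created by the consistency and predictivity
#' estimators; rarely called directly.
#'
#' @param per_unit Tibble with columns `animal_id`, `unit`, `value`,
#'   `n_valid`, `n_total`, `dropped`.
#' @param diagnostics Tibble of per-split/bootstrap term summaries.
#' @param metadata Named list echoing the mapping spec and plans.
#' @return A `consistency_result`.
#' @export
consistency_result <- function(per_unit, diagnostics = tibble(), metadata = list()) {
  vals <- per_unit$value[!per_unit$dropped]
  if (!length(vals)) abort("all units were excluded; no median can be formed.")
  structure(list(per_unit = per_unit, diagnostics = diagnostics,
                 median = median(vals), sem = sd(vals) / sqrt(length(vals)),
                 n_units = length(vals),
                 n_dropped = sum(per_unit$dropped),
                 metadata = metadata),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("<consistency_result> %s\n", x$metadata$label %||% ""))
  cat(sprintf("  median %.4f +/- %.4f s.e.m. across %d units (%d dropped)\n",
              x$median, x$sem, x$n_units, x$n_dropped))
  invisible(x)
}

#' Tidy a consistency result into its per-unit table
#'
#' @param x A `consistency_result`.
#' @param ... Unused.
#' @return The per-unit tibble (one averaged corrected value per target unit).
#' @export
tidy.consistency_result <- function(x, ...) x$per_unit

#' One-row summary of a consistency result
#'
#' @param x A `consistency_result`.
#' @param ... Unused.
#' @return Tibble with `median`, `sem`, `n_units`, `n_dropped`.
#' @export
glance.consistency_result <- function(x, ...) {
  tibble(median = x$median, sem = x$sem,
         n_units = x$n_units, n_dropped = x$n_dropped)
}

#' Histogram of per-unit noise-corrected values
#'
#' @param object A `consistency_result`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consistency_result <- function(object, bins = 30, ...) {
  df <- object$per_unit[!object$per_unit$dropped, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = object$median, colour = "firebrick") +
    ggplot2::labs(x = "noise-corrected consistency (per unit)", y = "units",
                  title = object$metadata$label %||% NULL) +
    ggplot2::theme_minimal()
}

#' Concatenate per-unit values across target animals and summarize
#'
#' Pools the per-unit averaged corrected values of several results (units
#' concatenated across target animals) and returns the median and s.e.m.
#' across the pooled units, with excluded units reported separately.
#' Invariant to the order of the inputs.
#'
#' @param results A `consistency_result` or list of them.
#' @return List with `median`, `sem`, `per_unit` (pooled tibble), `n_units`,
#'   `n_dropped`.
#' @export
aggregate_units <- function(results) {
  if (inherits(results, "consistency_result")) results <- list(results)
  if (!length(results)) abort("`results` must be nonempty.")
  per_unit <- bind_rows(lapply(results, function(r) r$per_unit))
  vals <- per_unit$value[!per_unit$dropped]
  if (!length(vals)) abort("all units were excluded; no median can be formed.")
  list(median = median(vals), sem = sd(vals) / sqrt(length(vals)),
       per_unit = per_unit, n_units = length(vals),
       n_dropped = sum(per_unit$dropped))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
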