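#' Specify a source-to-target population mapping
#'
#' The mapping class used for all consistency and predictivity computations:
#' `identity` (pass-through, equal unit counts), `one_to_one` (each target
#' unit is predicted from its single best-correlated source unit with a
#' univariate least-squares rescaling), `ridge` (L2-penalized multivariate
#' regression with unpenalized intercept, penalty on the squared-error scale
#' so `ridge_penalty = 1` matches the usual `alpha = 1` convention), or
#' `pls` (partial least squares regression, default 25 components).
#'
#' Ridge and PLS are fit with an intercept and no feature standardization:
#' responses enter on a common trial-averaged scale. The PLS component count
#' is capped at `min(pls_components, n_train_stimuli - 1, n_source_units,
#' rank of the training design)` so small or degenerate problems stay
#' well-posed; cap events are recorded on the fitted object.
#'
#' @param kind One of `"pls"`, `"ridge"`, `"one_to_one"`, `"identity"`.
#' @param ridge_penalty Positive ridge penalty (default 1).
#' @param pls_components Requested PLS component count (default 25).
#' @param one_to_one_absolute If `TRUE`, the one-to-one screen maximizes
#'   `|r|` rather than signed `r` (default `FALSE`: "top correlated" is read
#'   as the signed maximum).
#' @return A `mapping_spec` object.
#' @export
mapping_spec <- function(kind = c("pls", "ridge", "one_to_one", "identity"),
                         ridge_penalty = 1, pls_components = 25,
                         one_to_one_absolute = FALSE) {
  kind <- match.arg(kind)
  if (ridge_penalty <= 0) abort("`ridge_penalty` must be positive.")
  pls_components <- check_count(pls_components, "pls_components")
  structure(list(kind = kind, ridge_penalty = ridge_penalty,
                 pls_components = pls_components,
                 one_to_one_absolute = isTRUE(one_to_one_absolute)),
            class = "mapping_spec")
}

#' Fit a population mapping on training stimuli
#'
#' @param source_train,target_train Numeric `stimuli x units` matrices with
#'   equal row counts (>= 2) and no missing values.
#' @param spec A [mapping_spec()].
#' @param train_stimulus_ids Optional identifiers of the training stimuli,
#'   stored on the fitted object.
#' @return A `fitted_map`; apply it with [predict()].
#' @export
fit_map <- function(source_train, target_train, spec = mapping_spec(),
                    train_stimulus_ids = NULL) {
  source_train <- check_matrix(source_train, "source_train")
  target_train <- check_matrix(target_train, "target_train")
  if (nrow(source_train) != nrow(target_train)) {
    abort("`source_train` and `target_train` must have the same stimulus count.")
  }
  if (nrow(source_train) < 2) abort("at least 2 training stimuli are required.")

  fit <- switch(spec$kind,
    identity = {
      if (ncol(source_train) != ncol(target_train)) {
        abort("identity mapping requires equal source and target unit counts.")
      }
      list()
    },
    one_to_one = fit_one_to_one(source_train, target_train, spec$one_to_one_absolute),
    ridge = fit_ridge(source_train, target_train, spec$ridge_penalty),
    pls = fit_pls(source_train, target_train, spec$pls_components)
  )
  structure(c(fit, list(spec = spec,
                        n_source_units = ncol(source_train),
                        n_target_units = ncol(target_train),
                        train_stimulus_ids = train_stimulus_ids)),
            class = "fitted_map")
}

#' Per-target-unit best-correlated source unit
#'
#' For each target unit, the index of the source unit with maximal Pearson
#' correlation on the training stimuli. Ties are broken by the lowest source
#' index; zero-variance target units get an `NA` assignment and are flagged.
#'
#' @inheritParams fit_map
#' @param absolute Maximize `|r|` instead of signed `r`.
#' @return A tibble with `target_unit`, `source_unit`, `correlation`.
#' @export
one_to_one_assignment <- function(source_train, target_train, absolute = FALSE) {
  source_train <- check_matrix(source_train, "source_train")
  target_train <- check_matrix(target_train, "target_train")
  sc <- sweep(source_train, 2, colMeans(source_train))
  tc <- sweep(target_train, 2, colMeans(target_train))
  sn <- sqrt(colSums(sc^2)); tn <- sqrt(colSums(tc^2))
  cmat <- crossprod(sc, tc)  # source x target
  cmat <- cmat / outer(sn, tn)
  cmat[sn == 0, ] <- NA_real_
  score <- if (absolute) abs(cmat) else cmat
  idx <- integer(ncol(tc)); rr <- numeric(ncol(tc))
  for (j in seq_len(ncol(tc))) {
    if (tn[j] == 0 || all(is.na(score[, j]))) {
      idx[j] <- NA_integer_; rr[j] <- NA_real_
    } else {
      idx[j] <- which.max(score[, j])  # which.max takes the first (lowest) index on ties
      rr[j] <- cmat[idx[j], j]
    }
  }
  tibble(target_unit = seq_len(ncol(tc)), source_unit = idx, correlation = rr)
}

fit_one_to_one <- function(source_train, target_train, absolute) {
  assign <- one_to_one_assignment(source_train, target_train, absolute)
  p <- nrow(assign)
  slope <- numeric(p); intercept <- numeric(p)
  for (j in seq_len(p)) {
    i <- assign$source_unit[j]
    if (is.na(i)) { slope[j] <- NA; intercept[j] <- NA; next }
    x <- source_train[, i]; y <- target_train[, j]
    vx <- var(x)
    slope[j] <- if (vx > 0) cov(x, y) / vx else 0
    intercept[j] <- mean(y) - slope[j] * mean(x)
  }
  list(assignment = assign, slope = slope, intercept = intercept)
}

# Closed-form ridge with unpenalized intercept via centering; reproduces the
# standard alpha-on-squared-coefficients convention exactly.
fit_ridge <- function(X, Y, alpha) {
  keep <- which(apply(X, 2, sd) > 0)  # zero-variance source units carry no signal
  Xk <- X[, keep, drop = FALSE]
  xm <- colMeans(Xk); ym <- colMeans(Y)
  Xc <- sweep(Xk, 2, xm); Yc <- sweep(Y, 2, ym)
  p <- ncol(Xc)
  B <- solve(crossprod(Xc) + diag(alpha, p), crossprod(Xc, Yc))
  list(coef = B, x_mean = xm, y_mean = ym, keep = keep)
}

fit_pls <- function(X, Y, ncomp_requested) {
  keep <- which(apply(X, 2, sd) > 0)
  Xk <- X[, keep, drop = FALSE]
  rank_bound <- qr(sweep(Xk, 2, colMeans(Xk)))$rank
  ncomp <- min(ncomp_requested, nrow(Xk) - 1L, ncol(Xk), rank_bound)
  ncomp <- max(ncomp, 1L)
  capped <- ncomp < ncomp_requested
  colnames(Xk) <- paste0("s", seq_len(ncol(Xk)))
  # constant target units break the NIPALS deflation; predict their mean
  y_sd <- apply(Y, 2, sd)
  ykeep <- which(y_sd > 0)
  y_mean <- colMeans(Y)
  fit <- NULL
  if (length(ykeep)) {
    Yk <- Y[, ykeep, drop = FALSE]
    colnames(Yk) <- paste0("t", seq_len(ncol(Yk)))
    # the NIPALS eigen step can fail when ncomp touches the effective rank of
    # near-collinear data; back off one component at a time
    while (is.null(fit) && ncomp >= 1) {
      fit <- tryCatch(
        withCallingHandlers(
          mixOmics::pls(Xk, Yk, ncomp = ncomp, mode = "regression", scale = FALSE),
          warning = function(w) {
            # NIPALS convergence chatter at boundary component counts
            if (grepl("did not converge", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          }),
        error = function(e) NULL)
      if (is.null(fit)) {
        ncomp <- ncomp - 1L
        capped <- TRUE
      }
    }
    if (is.null(fit)) abort("PLS fit failed at every component count.")
  }
  list(pls_fit = fit, keep = keep, y_keep = ykeep, y_mean = y_mean,
       ncomp = ncomp, component_capped = capped)
}

#' Predict target responses from a fitted mapping
#'
#' @param object A `fitted_map` from [fit_map()].
#' @param source_test Numeric matrix with the same source-unit columns as the
#'   training source.
#' @param ... Unused.
#' @return `stimuli x target_units` prediction matrix.
#' @export
predict.fitted_map <- function(object, source_test, ...) {
  source_test <- check_matrix(source_test, "source_test")
  if (ncol(source_test) != object$n_source_units) {
    abort("`source_test` column count must match the training source.")
  }
  switch(object$spec$kind,
    identity = source_test,
    one_to_one = {
      p <- object$n_target_units
      out <- matrix(NA_real_, nrow(source_test), p)
      for (j in seq_len(p)) {
        i <- object$assignment$source_unit[j]
        if (!is.na(i)) out[, j] <- object$intercept[j] + object$slope[j] * source_test[, i]
      }
      out
    },
    ridge = {
      Xc <- sweep(source_test[, object$keep, drop = FALSE], 2, object$x_mean)
      sweep(Xc %*% object$coef, 2, object$y_mean, `+`)
    },
    pls = {
      out <- matrix(rep(object$y_mean, each = nrow(source_test)),
                    nrow(source_test), length(object$y_mean))
      if (!is.null(object$pls_fit)) {
        Xt <- source_test[, object$keep, drop = FALSE]
        colnames(Xt) <- paste0("s", seq_len(ncol(Xt)))
        pr <- predict(object$pls_fit, Xt)$predict
        out[, object$y_keep] <- pr[, , object$ncomp]
      }
      out
    }
  )
}

#' @export
print.fitted_map <- function(x, ...) {
  cat(sprintf("<fitted_map> %s: %d source units -> %d target units\n",
              x$spec$kind, x$n_source_units, x$n_target_units))
  if (x$spec$kind == "pls") {
    cat(sprintf("  components used: %d%s\n", x$ncomp,
                if (isTRUE(x$component_capped)) " (capped)" else ""))
  }
  invisible(x)
}
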