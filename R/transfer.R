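#' Regularization grid for linear readouts
#'
#' The standard grid of SVM cost values `C` used for the linear transfer
#' readouts; ridge regressions use `alpha = 1 / C` over the same grid.
#'
#' @return Numeric vector of 31 cost values from `1e-8` to `5e8`.
#' @export
regularization_grid <- function() {
  base <- 10^seq(-8, 8)
  sort(unique(c(base, 5 * base)))[1:31]
}

#' Linear transfer evaluation of model feature layers
#'
#' Scores each layer on a downstream task through a linear readout:
#' features are reduced to `pca_dim` dimensions by PCA when wider (PCA fit on
#' the training portion of each outer split only), then a linear max-margin
#' classifier (cost `C` chosen by inner k-fold cross-validation over
#' `C_grid`) or a ridge regression (`alpha = 1/C` over the same grid) is fit
#' on the train split and scored on the test split. Scores are averaged over
#' category-balanced outer train/test splits; the best layer is reported.
#'
#' @param features A [model_feature_set()] or a single `samples x features`
#'   matrix.
#' @param targets Class labels (factor/character, classification) or a
#'   numeric vector/matrix of continuous targets (regression).
#' @param task_kind `"classification"` or `"regression"`.
#' @param n_outer_splits Number of outer train/test splits (default 10).
#' @param inner_folds Folds for the inner CV choosing `C` (default 5).
#' @param train_fraction Fraction of samples in each outer train split.
#' @param pca_dim Maximum feature dimensionality before the readout
#'   (default 1000).
#' @param C_grid Cost grid (default [regularization_grid()]).
#' @param seed Seed for all splits.
#' @return A `transfer_result`: `by_layer` tibble (`layer`, `score`, `sem`),
#'   `best_layer`, `task_kind`. Scores are mean accuracy (classification) or
#'   mean Pearson correlation across target dimensions (regression).
#' @export
linear_transfer_evaluation <- function(features, targets,
                                       task_kind = c("classification", "regression"),
                                       n_outer_splits = 10, inner_folds = 5,
                                       train_fraction = 0.75, pca_dim = 1000,
                                       C_grid = regularization_grid(), seed = 1) {
  task_kind <- match.arg(task_kind)
  if (is.matrix(features)) features <- model_feature_set(list(layer_1 = features))
  n <- nrow(features$layers[[1]])
  if (task_kind == "classification") {
    targets <- as.factor(targets)
    if (length(targets) != n) abort("`targets` length must match feature rows.")
  } else {
    targets <- as.matrix(targets)
    if (nrow(targets) != n) abort("`targets` rows must match feature rows.")
  }
  if (n < inner_folds) abort("fewer samples than inner folds.")

  scores <- matrix(NA_real_, n_outer_splits, length(features$layers),
                   dimnames = list(NULL, names(features$layers)))
  for (s in seq_len(n_outer_splits)) {
    idx <- outer_split(targets, task_kind, train_fraction,
                       seed = derive_seed(seed, 40 + s))
    for (nm in names(features$layers)) {
      X <- features$layers[[nm]]
      Xtr <- X[idx$train, , drop = FALSE]
      Xte <- X[idx$test, , drop = FALSE]
      if (ncol(Xtr) > pca_dim) {
        pc <- prcomp(Xtr, center = TRUE, scale. = FALSE, rank. = pca_dim)
        Xtr <- pc$x
        Xte <- sweep(Xte, 2, pc$center) %*% pc$rotation
      }
      scores[s, nm] <- if (task_kind == "classification") {
        fit_linear_classifier(Xtr, targets[idx$train], Xte, targets[idx$test],
                              C_grid, inner_folds,
                              seed = derive_seed(seed, 90 + s))
      } else {
        fit_ridge_readout(Xtr, targets[idx$train, , drop = FALSE],
                          Xte, targets[idx$test, , drop = FALSE],
                          C_grid, inner_folds,
                          seed = derive_seed(seed, 90 + s))
      }
    }
  }
  by_layer <- tibble(layer = colnames(scores),
                     score = colMeans(scores),
                     sem = apply(scores, 2, sd) / sqrt(nrow(scores)))
  structure(list(by_layer = by_layer,
                 best_layer = by_layer$layer[which.max(by_layer$score)],
                 task_kind = task_kind, per_split = scores),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s; best layer: %s\n", x$task_kind, x$best_layer))
  print(x$by_layer)
  invisible(x)
}

#' @export
tidy.transfer_result <- function(x, ...) x$by_layer

outer_split <- function(targets, task_kind, train_fraction, seed) {
  n <- if (is.matrix(targets)) nrow(targets) else length(targets)
  with_seed(seed, {
    if (task_kind == "classification") {
      train <- integer(0)
      for (lv in levels(targets)) {
        members <- which(targets == lv)
        k <- max(1L, round(train_fraction * length(members)))
        train <- c(train, sample(members, k))
      }
      train <- sort(train)
    } else {
      train <- sort(sample.int(n, round(train_fraction * n)))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

inner_folds_of <- function(y, k, seed) {
  n <- if (is.matrix(y)) nrow(y) else length(y)
  with_seed(seed, {
    if (is.factor(y)) {
      fold <- integer(n)
      for (lv in levels(y)) {
        members <- sample(which(y == lv))
        fold[members] <- rep_len(seq_len(k), length(members))
      }
      fold
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })
}

fit_linear_classifier <- function(Xtr, ytr, Xte, yte, C_grid, inner_folds, seed) {
  fold <- inner_folds_of(ytr, inner_folds, seed)
  cv_acc <- vapply(C_grid, function(C) {
    accs <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      if (length(unique(ytr[tr])) < 2) return(NA_real_)
      m <- e1071::svm(Xtr[tr, , drop = FALSE], droplevels(ytr[tr]),
                      kernel = "linear", cost = C, scale = FALSE)
      mean(as.character(predict(m, Xtr[!tr, , drop = FALSE])) == as.character(ytr[!tr]))
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  C_best <- C_grid[which.max(cv_acc)]
  m <- e1071::svm(Xtr, ytr, kernel = "linear", cost = C_best, scale = FALSE)
  mean(as.character(predict(m, Xte)) == as.character(yte))
}

fit_ridge_readout <- function(Xtr, ytr, Xte, yte, C_grid, inner_folds, seed) {
  fold <- inner_folds_of(ytr[, 1], inner_folds, seed)
  alphas <- 1 / C_grid
  cv_cor <- vapply(alphas, function(a) {
    cors <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      fit <- fit_ridge(Xtr[tr, , drop = FALSE], ytr[tr, , drop = FALSE], a)
      pred <- ridge_predict(fit, Xtr[!tr, , drop = FALSE])
      mean(corr_columns(pred, ytr[!tr, , drop = FALSE]), na.rm = TRUE)
    }, numeric(1))
    mean(cors, na.rm = TRUE)
  }, numeric(1))
  a_best <- alphas[which.max(cv_cor)]
  fit <- fit_ridge(Xtr, ytr, a_best)
  mean(corr_columns(ridge_predict(fit, Xte), yte), na.rm = TRUE)
}

ridge_predict <- function(fit, X) {
  Xc <- sweep(X[, fit$keep, drop = FALSE], 2, fit$x_mean)
  sweep(Xc %*% fit$coef, 2, fit$y_mean, `+`)
}
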