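test_that("an oracle layer scores near 1 and pure noise near 0, ordering the layers", {
  sim <- generate_cohort(n_animals = 2, n_units = 30, n_stimuli = 118,
                         n_trials = 50, n_latent = 8, noise_sd = 1, seed = 71)
  feats <- generate_model_features(sim$ground_truth,
                                   list(clean = list(n_features = 20, corruption = 0),
                                        noise = list(n_features = 20, corruption = 1)),
                                   seed = 3)
  res <- model_neural_predictivity(feats, sim$recordings, mapping_spec("pls"),
                                   split_half_plan(10, seed = 2),
                                   stimulus_split_plan(n_splits = 3, seed = 4))
  by <- res$by_layer
  expect_equal(res$best_layer, "clean")
  expect_lt(abs(by$median[by$layer == "clean"] - 1), 0.05)
  expect_lt(abs(by$median[by$layer == "noise"]), 0.1)
  expect_true(all(c("tbl_df") %in% class(tidy(res))))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("predictivity of the oracle layer dominates every corrupted layer", {
  sim <- generate_cohort(n_animals = 1, n_units = 25, n_stimuli = 80,
                         n_trials = 20, n_latent = 6, noise_sd = 1, seed = 72)
  feats <- generate_model_features(sim$ground_truth,
                                   list(c0 = list(n_features = 12, corruption = 0),
                                        c5 = list(n_features = 12, corruption = 0.5),
                                        c9 = list(n_features = 12, corruption = 0.9)),
                                   seed = 5)
  res <- model_neural_predictivity(feats, sim$recordings[[1]], mapping_spec("ridge"),
                                   split_half_plan(4, seed = 2),
                                   stimulus_split_plan(n_splits = 2, seed = 4))
  med <- res$by_layer$median
  expect_equal(res$best_layer, "c0")
  expect_gt(med[1], med[2] - 0.03)
  expect_gt(med[2], med[3] - 0.03)
})

test_that("feature/recording stimulus alignment is enforced", {
  sim <- small_cohort(seed = 73)
  feats <- model_feature_set(list(a = matrix(rnorm(10 * 4), 10, 4)))
  expect_error(model_neural_predictivity(feats, sim$recordings), "aligned")
})

test_that("preprocessing regimes produce the documented geometries", {
  skip_if_not_installed("EBImage")
  img <- matrix(seq(0, 1, length.out = 918 * 1174), 918, 1174)
  out <- preprocess_stimulus_images(img, "cifar_trained")
  expect_equal(dim(out), c(64L, 81L))

  sq <- matrix(runif(300 * 300), 300, 300)
  out2 <- preprocess_stimulus_images(sq, "imagenet_trained")
  expect_equal(dim(out2), c(64L, 64L))

  # deterministic and idempotent at target resolution
  again <- preprocess_stimulus_images(sq, "imagenet_trained")
  expect_identical(out2, again)
  expect_identical(preprocess_stimulus_images(out2, "cifar_trained"), out2)

  rgb <- array(runif(256 * 320 * 3), c(256, 320, 3))
  out3 <- preprocess_stimulus_images(rgb, "imagenet_trained")
  expect_equal(dim(out3), c(64L, 64L, 3L))

  expect_error(interanimal:::center_crop(matrix(0, 10, 10), 224), "smaller")
})

test_that("the center crop of an exactly-sized image is the image itself", {
  skip_if_not_installed("EBImage")
  img <- matrix(runif(224 * 224), 224, 224)
  expect_identical(interanimal:::center_crop(img, 224), img)
})

test_that("linearly separable classes reach near-perfect transfer accuracy", {
  set.seed(74)
  n <- 80; d <- 5
  labels <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * d), n, d)
  X[labels == "a", 1] <- X[labels == "a", 1] + 8
  res <- linear_transfer_evaluation(X, labels, "classification",
                                    n_outer_splits = 3, C_grid = c(0.01, 1, 100),
                                    seed = 5)
  expect_gte(res$by_layer$score, 0.99)
})

test_that("a realizable linear regression target is recovered almost exactly", {
  set.seed(75)
  X <- matrix(rnorm(300), 60, 5)
  y <- X %*% c(1, -2, 0.5, 3, -1)
  res <- linear_transfer_evaluation(X, y, "regression",
                                    n_outer_splits = 3, C_grid = c(1, 1e4),
                                    seed = 6)
  expect_gte(res$by_layer$score, 0.99)
})

test_that("shuffled labels on balanced classes give chance-level accuracy", {
  set.seed(76)
  n <- 160; k <- 8
  labels <- factor(rep(seq_len(k), each = n / k))
  shuffled <- sample(labels)
  X <- matrix(rnorm(n * 10), n, 10)
  res <- linear_transfer_evaluation(X, shuffled, "classification",
                                    n_outer_splits = 4, C_grid = c(0.1, 10),
                                    seed = 7)
  # binomial error around 1/8 on 40-sample test splits across 4 splits
  expect_lt(abs(res$by_layer$score - 1 / k), 0.12)
})

test_that("PCA reduction is fit on the training portion and caps the width", {
  set.seed(77)
  n <- 40
  labels <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * 30), n, 30)
  X[labels == "a", 1] <- X[labels == "a", 1] + 6
  res <- linear_transfer_evaluation(X, labels, "classification",
                                    n_outer_splits = 2, pca_dim = 5,
                                    C_grid = c(1), seed = 8)
  expect_gte(res$by_layer$score, 0.9)
  res_rep <- linear_transfer_evaluation(X, labels, "classification",
                                        n_outer_splits = 2, pca_dim = 5,
                                        C_grid = c(1), seed = 8)
  expect_identical(res$per_split, res_rep$per_split)
})
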