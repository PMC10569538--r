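test_that("cross-entropy on uniform logits equals log of the class count", {
  for (C in c(4, 10, 1000)) {
    logits <- matrix(0, 3, C)
    expect_equal(loss_cross_entropy(logits, c(0, 1, C - 1)), log(C), tolerance = 1e-12)
  }
  # shifting logits by a constant leaves the loss unchanged
  set.seed(91)
  L <- matrix(rnorm(40), 4, 10)
  expect_equal(loss_cross_entropy(L, c(0, 3, 5, 9)),
               loss_cross_entropy(L + 100, c(0, 3, 5, 9)), tolerance = 1e-9)
  expect_error(loss_cross_entropy(L, c(0, 1, 2, 10)), "labels")
})

test_that("sparse autoencoder loss matches its printed normalizations", {
  x <- rep(0, 64^2)
  expect_equal(loss_sparse_autoencoder(x, x, rep(0, 128)), 0)
  # f(x) = x + 1 elementwise, ||v||_1 = 128, lambda = 5e-4 -> 1/2 + 5e-4
  v <- rep(1, 128)
  expect_equal(loss_sparse_autoencoder(x, x + 1, v, lambda = 5e-4),
               0.5 + 5e-4, tolerance = 1e-12)
  expect_error(loss_sparse_autoencoder(x, x, v, lambda = -1), "nonnegative")
})

test_that("depth loss normalizes the target map to zero mean unit sd", {
  set.seed(92)
  depth <- matrix(rnorm(2 * 100, mean = 5, sd = 3), 2, 100)
  # predicting the normalized map exactly gives zero loss
  dn <- t(apply(depth, 1, function(r) (r - mean(r)) / (sd(r) * sqrt(99 / 100))))
  expect_equal(loss_depth_mse(dn, depth), 0, tolerance = 1e-12)
  expect_gt(loss_depth_mse(dn * 0, depth), 0.9)
})

test_that("instance recognition loss behaves and its bank update is a fixed point", {
  set.seed(93)
  z <- c(1, rep(0, 7))
  v <- z
  negs <- diag(8)[2:5, ]
  out <- loss_instance_recognition(z, v, negs, bank_size = 100)
  expect_true(is.finite(out$loss) && out$loss > 0)
  # explicit Z override is honored
  out2 <- loss_instance_recognition(z, v, negs, bank_size = 100, Z = out$Z)
  expect_equal(out$loss, out2$loss, tolerance = 1e-12)

  expect_equal(memory_bank_update(v, v), v, tolerance = 1e-12)
})

test_that("IR loss decreases monotonically as z approaches its bank entry", {
  target <- c(1, rep(0, 7))
  away <- c(0, 1, rep(0, 6))
  negs <- diag(8)[3:6, ]
  Z <- 50
  losses <- vapply(seq(0, 1, length.out = 10), function(a) {
    z <- (1 - a) * away + a * target
    z <- z / sqrt(sum(z^2))
    loss_instance_recognition(z, target, negs, bank_size = 100, Z = Z)$loss
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("bank momentum update converges geometrically with ratio 0.5", {
  v0 <- c(1, rep(0, 7))
  z <- c(0, 1, rep(0, 6))
  pre_norm <- function(v) 0.5 * v + 0.5 * z
  d1 <- sqrt(sum((pre_norm(v0) - z)^2))
  expect_equal(d1 / sqrt(sum((v0 - z)^2)), 0.5, tolerance = 1e-12)
  # iterating the full (renormalized) update approaches z
  v <- v0
  dists <- vapply(1:6, function(i) {
    v <<- memory_bank_update(v, z)
    sqrt(sum((v - z)^2))
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
})

test_that("momentum-queue loss matches the orthogonal-queue closed form", {
  v <- c(1, rep(0, 7))
  queue <- diag(8)[2:8, ]  # 7 negatives orthogonal to v
  out <- loss_moco(v, v, queue, tau = 0.2)
  expect_equal(out$loss, -log(exp(5) / (exp(5) + 7 * exp(0))), tolerance = 1e-12)
  # queue update enqueues k0 and dequeues the oldest
  expect_equal(nrow(out$queue), 7)
  expect_equal(out$queue[7, ], v)
  expect_equal(out$queue[1, ], queue[2, ])
  th <- momentum_encoder_update(rep(0, 4), rep(1, 4), lambda = 0.999)
  expect_equal(th, rep(0.001, 4), tolerance = 1e-12)
})

test_that("batch contrastive loss equals log(2N - 1) for identical embeddings", {
  for (n in c(2, 4, 8)) {
    u <- c(1, rep(0, 5))
    z <- matrix(u, n, 6, byrow = TRUE)
    expect_equal(loss_simclr(z, z), log(2 * n - 1), tolerance = 1e-10)
  }
  expect_error(loss_simclr(matrix(1, 1, 4), matrix(1, 1, 4)), "at least 2")
})

test_that("batch contrastive loss is invariant to batch permutation", {
  set.seed(94)
  z1 <- matrix(rnorm(6 * 8), 6, 8); z1 <- z1 / sqrt(rowSums(z1^2))
  z2 <- matrix(rnorm(6 * 8), 6, 8); z2 <- z2 / sqrt(rowSums(z2^2))
  perm <- sample(6)
  expect_equal(loss_simclr(z1, z2), loss_simclr(z1[perm, ], z2[perm, ]),
               tolerance = 1e-10)
})

test_that("negative-cosine loss is bounded and hits -1 for aligned views", {
  u <- c(0.6, 0.8)
  expect_equal(loss_simsiam(u, u, u, u), -1, tolerance = 1e-12)
  set.seed(95)
  p1 <- matrix(rnorm(10), 5, 2); p2 <- matrix(rnorm(10), 5, 2)
  z1 <- matrix(rnorm(10), 5, 2); z2 <- matrix(rnorm(10), 5, 2)
  val <- loss_simsiam(p1, p2, z1, z2)
  expect_gte(val, -1); expect_lte(val, 1)
})

test_that("cross-correlation loss vanishes on a whitened identical batch and is nonnegative", {
  z <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))  # orthogonal equal-norm columns
  C <- crossprod(z, z) / outer(sqrt(colSums(z^2)), sqrt(colSums(z^2)))
  expect_equal(C, diag(2), tolerance = 1e-12)
  expect_equal(loss_barlow_twins(z, z), 0, tolerance = 1e-12)
  set.seed(96)
  a <- matrix(rnorm(40), 10, 4); b <- matrix(rnorm(40), 10, 4)
  expect_gte(loss_barlow_twins(a, b), 0)
})

test_that("variance-invariance-covariance loss is zero only for spread whitened views", {
  set.seed(97)
  # whitened batch: zero-mean orthogonal columns at per-dimension sd 1.5
  H <- stats::contr.helmert(20)[, 1:10]
  z <- 1.5 * scale(H, center = FALSE, scale = apply(H, 2, sd))
  expect_lt(loss_vicreg(z, z), 1e-8)
  expect_gt(loss_vicreg(z, -z), 10)     # opposite views violate invariance
  collapsed <- matrix(0.001 * rnorm(200), 20, 10)
  expect_gt(loss_vicreg(collapsed, collapsed), 10)  # sd hinge fires
})

test_that("losses are permutation-invariant over batch order", {
  set.seed(98)
  L <- matrix(rnorm(50), 5, 10); lab <- c(0, 2, 4, 6, 8)
  perm <- sample(5)
  expect_equal(loss_cross_entropy(L, lab), loss_cross_entropy(L[perm, ], lab[perm]),
               tolerance = 1e-12)
  z1 <- matrix(rnorm(30), 6, 5); z2 <- matrix(rnorm(30), 6, 5)
  expect_equal(loss_barlow_twins(z1, z2), loss_barlow_twins(z1[perm6 <- sample(6), ], z2[perm6, ]),
               tolerance = 1e-12)
  expect_equal(loss_vicreg(z1, z2), loss_vicreg(z1[perm6, ], z2[perm6, ]),
               tolerance = 1e-12)
})
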