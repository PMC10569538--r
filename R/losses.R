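#' Supervised cross-entropy loss
#'
#' Mean over the batch of `-log softmax(logits)[label]`, labels zero-indexed.
#' Uniform logits over `C` classes give exactly `log(C)`.
#'
#' @param logits `N x C` numeric matrix of model outputs.
#' @param labels Integer vector in `[0, C - 1]`, one per row.
#' @return Scalar loss.
#' @export
loss_cross_entropy <- function(logits, labels) {
  logits <- check_matrix(logits, "logits")
  if (length(labels) != nrow(logits)) abort("one label per logit row is required.")
  if (any(labels < 0 | labels >= ncol(logits))) {
    abort("labels must lie in [0, n_classes - 1].")
  }
  # row-wise log-sum-exp with max shift for stability
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  picked <- logits[cbind(seq_len(nrow(logits)), labels + 1L)]
  mean(lse - picked)
}

#' Sparse autoencoder reconstruction loss
#'
#' `1 / (2 * 64^2) * ||f(x) - x||^2 + lambda / 128 * ||v||_1`, averaged over
#' the batch: a squared reconstruction error scaled by twice the pixel count
#' of a 64 x 64 image plus an L1 sparsity penalty on the 128-dimensional
#' embedding, each with the printed normalizations.
#'
#' @param x,reconstruction Matrices (`batch x pixels`) or vectors of original
#'   and reconstructed images.
#' @param v Embedding matrix (`batch x embedding_dim`) or vector.
#' @param lambda Nonnegative sparsity coefficient (default 5e-4).
#' @param image_side Image side used in the reconstruction scaling
#'   (default 64).
#' @param embedding_dim Divisor of the sparsity term (default 128).
#' @return Scalar loss.
#' @export
loss_sparse_autoencoder <- function(x, reconstruction, v, lambda = 5e-4,
                                    image_side = 64, embedding_dim = 128) {
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  x <- rbind(x); reconstruction <- rbind(reconstruction); v <- rbind(v)
  if (!all(dim(x) == dim(reconstruction))) abort("`x` and `reconstruction` shapes differ.")
  if (nrow(v) != nrow(x)) abort("`v` must have one row per batch example.")
  recon <- rowSums((reconstruction - x)^2) / (2 * image_side^2)
  sparse <- lambda * rowSums(abs(v)) / embedding_dim
  mean(recon + sparse)
}

#' Depth-prediction mean-squared loss
#'
#' Normalizes each target depth map to zero mean and unit standard deviation
#' across pixels, then takes the mean squared error against the prediction.
#'
#' @param prediction,depth Matrices (`batch x pixels`) or vectors.
#' @return Scalar loss.
#' @export
loss_depth_mse <- function(prediction, depth) {
  prediction <- rbind(prediction); depth <- rbind(depth)
  if (!all(dim(prediction) == dim(depth))) abort("shapes differ.")
  dn <- t(apply(depth, 1, function(r) {
    s <- sd(r) * sqrt((length(r) - 1) / length(r))  # population sd across pixels
    if (s == 0) abort("constant depth map cannot be normalized.")
    (r - mean(r)) / s
  }))
  mean((prediction - dn)^2)
}

# unit-normalize rows, warning when they were not normalized already
normalize_rows <- function(z, name) {
  z <- rbind(z)
  n <- sqrt(rowSums(z^2))
  if (any(n == 0)) abort(sprintf("`%s` contains zero vectors.", name))
  if (any(abs(n - 1) > 1e-6)) {
    warn(sprintf("`%s` was not unit-normalized; normalizing.", name))
    z <- z / n
  }
  z
}

#' Instance-recognition contrastive loss with a memory bank
#'
#' Noise-contrastive loss over a memory bank of per-image embeddings:
#' `h(u) = (exp(u.z / tau) / Z) / (exp(u.z / tau) / Z + m / N)` and
#' `L = -log h(v) - sum_j log(1 - h(v_j))` for the positive bank entry `v`
#' and `m` negatives sampled from the bank. The normalization constant `Z`
#' is estimated once as `N * mean(exp(u.z / tau))` over a sample of bank
#' entries and then frozen (pass `Z` to override); this estimate is a
#' documented stand-in for the constant left unspecified in the objective.
#'
#' @param z Current embedding of the image (unit-norm vector).
#' @param v Its stored memory-bank embedding (unit-norm vector).
#' @param negatives `m x d` matrix of negative bank embeddings.
#' @param bank_size Total bank size `N` (defaults to `m + 1`).
#' @param tau Temperature (default 0.07).
#' @param Z Optional explicit normalization constant.
#' @param z_sample Optional matrix of bank entries used to estimate `Z`
#'   (defaults to `rbind(v, negatives)`).
#' @return List with `loss` and the frozen `Z`.
#' @export
loss_instance_recognition <- function(z, v, negatives, bank_size = NULL,
                                      tau = 0.07, Z = NULL, z_sample = NULL) {
  if (tau <= 0) abort("`tau` must be positive.")
  z <- drop(normalize_rows(z, "z")); v <- drop(normalize_rows(v, "v"))
  negatives <- normalize_rows(negatives, "negatives")
  if (!nrow(negatives)) abort("at least one negative is required.")
  m <- nrow(negatives)
  N <- bank_size %||% (m + 1)
  if (is.null(Z)) {
    smp <- z_sample %||% rbind(v, negatives)
    Z <- N * mean(exp(smp %*% z / tau))
  }
  h <- function(u) {
    e <- exp(sum(u * z) / tau) / Z
    e / (e + m / N)
  }
  hn <- apply(negatives, 1, h)
  list(loss = -log(h(v)) - sum(log(1 - hn)), Z = Z)
}

#' Memory-bank momentum update
#'
#' `v <- lambda * v + (1 - lambda) * z`, then re-projection onto the unit
#' sphere. With `z` fixed, repeated updates approach `z` geometrically
#' (ratio `lambda` per step before renormalization).
#'
#' @param v Stored bank embedding.
#' @param z Current embedding.
#' @param lambda Momentum coefficient (default 0.5).
#' @return Updated unit-norm embedding.
#' @export
memory_bank_update <- function(v, z, lambda = 0.5) {
  u <- lambda * v + (1 - lambda) * z
  u / sqrt(sum(u^2))
}

#' Momentum-queue contrastive loss
#'
#' InfoNCE over a queue of negatives:
#' `L = -log( exp(v.k0 / tau) / sum_{i=0}^{K} exp(v.ki / tau) )` where `v`
#' is the query embedding, `k0` the positive key and the queue holds the `K`
#' negatives. Also applies the queue and key-encoder momentum updates.
#'
#' @param v Query embedding (unit norm).
#' @param k0 Positive key embedding (unit norm).
#' @param queue `K x d` matrix of negative key embeddings (the dictionary).
#' @param tau Temperature (default 0.2).
#' @return List with `loss` and `queue` (k0 enqueued, oldest entry dequeued).
#' @export
loss_moco <- function(v, k0, queue, tau = 0.2) {
  if (tau <= 0) abort("`tau` must be positive.")
  v <- drop(normalize_rows(v, "v")); k0 <- drop(normalize_rows(k0, "k0"))
  queue <- normalize_rows(queue, "queue")
  if (!nrow(queue)) abort("the negative queue is empty.")
  logits <- c(sum(v * k0), queue %*% v) / tau
  mx <- max(logits)
  loss <- -(logits[1] - (mx + log(sum(exp(logits - mx)))))
  list(loss = loss, queue = rbind(queue[-1, , drop = FALSE], k0))
}

#' Key-encoder momentum update
#'
#' `theta_k <- lambda * theta_k + (1 - lambda) * theta_q` with
#' `lambda = 0.999` by default; only the query parameters follow gradients.
#'
#' @param theta_k,theta_q Numeric vectors/arrays of equal shape.
#' @param lambda Momentum coefficient.
#' @return Updated key parameters.
#' @export
momentum_encoder_update <- function(theta_k, theta_q, lambda = 0.999) {
  if (!all(dim(rbind(theta_k)) == dim(rbind(theta_q)))) abort("parameter shapes differ.")
  lambda * theta_k + (1 - lambda) * theta_q
}

#' Batchwise contrastive loss over paired augmentations
#'
#' For a batch of `N` images with two augmented views each (`2N` unit-norm
#' embeddings), every view is an anchor whose positive is its partner view:
#' `L = -log( exp(z_a . z_p / tau) / sum_{i != a} exp(z_a . z_i / tau) )`,
#' averaged over all `2N` anchors. If every embedding is identical the loss
#' is exactly `log(2N - 1)`.
#'
#' @param z1,z2 `N x d` matrices of the two views' embeddings (`N >= 2`).
#' @param tau Temperature (default 0.1).
#' @return Scalar loss.
#' @export
loss_simclr <- function(z1, z2, tau = 0.1) {
  if (tau <= 0) abort("`tau` must be positive.")
  z1 <- rbind(z1); z2 <- rbind(z2)
  if (!all(dim(z1) == dim(z2))) abort("paired views must have equal shapes.")
  n <- nrow(z1)
  if (n < 2) abort("batch size must be at least 2.")
  z1 <- normalize_rows(z1, "z1"); z2 <- normalize_rows(z2, "z2")
  z <- rbind(z1, z2)                     # view order: 1..N, partners N+1..2N
  sim <- tcrossprod(z) / tau
  partner <- c(n + seq_len(n), seq_len(n))
  losses <- vapply(seq_len(2 * n), function(a) {
    others <- sim[a, -a]
    mx <- max(others)
    -(sim[a, partner[a]] - (mx + log(sum(exp(others - mx)))))
  }, numeric(1))
  mean(losses)
}

#' Negative-cosine similarity loss with stop-gradient semantics
#'
#' `L = -1/2 (cos(p1, z2) + cos(p2, z1))`. The stop-gradient on `z1`, `z2`
#' is a gradient contract and does not change the value, which lies in
#' `[-1, 1]`; perfectly aligned unit vectors give exactly -1.
#'
#' @param p1,p2 Predictor outputs for the two views (`N x d` or vectors).
#' @param z1,z2 Projector outputs for the two views.
#' @return Scalar loss.
#' @export
loss_simsiam <- function(p1, p2, z1, z2) {
  p1 <- rbind(p1); p2 <- rbind(p2); z1 <- rbind(z1); z2 <- rbind(z2)
  if (!all(dim(p1) == dim(z2)) || !all(dim(p2) == dim(z1))) {
    abort("paired views must have equal shapes.")
  }
  cosine <- function(a, b) {
    rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  }
  mean(-0.5 * (cosine(z1, p2) + cosine(z2, p1)))
}

#' Redundancy-reduction (cross-correlation) loss
#'
#' Builds the cross-correlation matrix
#' `C_ij = sum_b z1[b,i] z2[b,j] / (||z1[,i]|| ||z2[,j]||)` between the twin
#' embeddings and penalizes its distance from the identity:
#' `sum_i (1 - C_ii)^2 + lambda * sum_{i != j} C_ij^2`.
#'
#' @param z1,z2 `N x d` embedding matrices of the two views (`N >= 2`).
#' @param lambda Off-diagonal coefficient (default 0.0051).
#' @return Scalar loss (nonnegative).
#' @export
loss_barlow_twins <- function(z1, z2, lambda = 0.0051) {
  z1 <- rbind(z1); z2 <- rbind(z2)
  if (!all(dim(z1) == dim(z2))) abort("paired views must have equal shapes.")
  if (nrow(z1) < 2) abort("batch size must be at least 2.")
  n1 <- sqrt(colSums(z1^2)); n2 <- sqrt(colSums(z2^2))
  if (any(n1 == 0) || any(n2 == 0)) abort("zero-variance embedding dimension.")
  C <- crossprod(z1, z2) / outer(n1, n2)
  on_diag <- sum((1 - diag(C))^2)
  off_diag <- sum(C^2) - sum(diag(C)^2)
  on_diag + lambda * off_diag
}

#' Variance-invariance-covariance regularization loss
#'
#' Three-term objective on twin embeddings: an invariance term (mean squared
#' distance between the views), a variance term (hinge keeping each
#' dimension's standard deviation above 1 in both views), and a covariance
#' term (off-diagonal covariance pushed to zero, scaled by the embedding
#' dimension). Coefficients default to the reference implementation's
#' (25, 25, 1); the objective's source text names the terms without printing
#' a formula, so these weights are not taken from it.
#'
#' @param z1,z2 `N x d` embedding matrices (`N >= 2`).
#' @param sim_coeff,std_coeff,cov_coeff Term coefficients.
#' @return Scalar loss.
#' @export
loss_vicreg <- function(z1, z2, sim_coeff = 25, std_coeff = 25, cov_coeff = 1) {
  z1 <- rbind(z1); z2 <- rbind(z2)
  if (!all(dim(z1) == dim(z2))) abort("paired views must have equal shapes.")
  n <- nrow(z1); d <- ncol(z1)
  if (n < 2) abort("batch size must be at least 2.")
  invariance <- mean((z1 - z2)^2)
  hinge <- function(z) {
    s <- sqrt(apply(z, 2, var) + 1e-4)
    mean(pmax(0, 1 - s))
  }
  variance <- (hinge(z1) + hinge(z2)) / 2
  covterm <- function(z) {
    zc <- sweep(z, 2, colMeans(z))
    C <- crossprod(zc) / (n - 1)
    (sum(C^2) - sum(diag(C)^2)) / d
  }
  covariance <- (covterm(z1) + covterm(z2)) / 2
  sim_coeff * invariance + std_coeff * variance + cov_coeff * covariance
}
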