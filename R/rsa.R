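#' Representational dissimilarity matrix
#'
#' Computes the `stimuli x stimuli` RDM of a response matrix. The default
#' dissimilarity is `1 - Pearson correlation` between the two stimuli's
#' response vectors across units; a Euclidean-distance option is provided.
#' Stimuli whose response vector is constant across units have undefined
#' correlation-distance entries; these are returned as `NA` and flagged via
#' attribute `"constant_stimuli"`.
#'
#' @param responses Numeric `stimuli x units` matrix with at least 2 units.
#' @param method `"correlation"` (default) or `"euclidean"`.
#' @return Symmetric matrix with zero diagonal.
#' @export
compute_rdm <- function(responses, method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  responses <- check_matrix(responses, "responses")
  if (ncol(responses) < 2) abort("at least 2 units are required to form an RDM.")
  n <- nrow(responses)
  if (method == "euclidean") {
    rdm <- as.matrix(stats::dist(responses))
    dimnames(rdm) <- NULL
    attr(rdm, "constant_stimuli") <- integer(0)
    return(rdm)
  }
  xc <- responses - rowMeans(responses)
  norms <- unname(sqrt(rowSums(xc^2)))
  const <- which(norms == 0)
  cmat <- tcrossprod(xc) / outer(norms, norms)
  rdm <- 1 - cmat
  if (length(const)) {
    rdm[const, ] <- NA_real_
    rdm[, const] <- NA_real_
  }
  diag(rdm) <- 0
  attr(rdm, "constant_stimuli") <- const
  rdm
}

#' RSA score between two dissimilarity matrices
#'
#' Pearson correlation of the strict upper triangles (diagonals excluded) of
#' two equally sized RDMs. Entries undefined in either RDM are dropped
#' pairwise; a constant triangle signals an error.
#'
#' @param rdm_x,rdm_y Equal-shape square matrices (>= 3 stimuli).
#' @return Scalar correlation.
#' @export
rsa_score <- function(rdm_x, rdm_y) {
  if (!all(dim(rdm_x) == dim(rdm_y))) abort("RDMs must have equal shapes.")
  if (nrow(rdm_x) < 3) abort("at least 3 stimuli are required for an RSA score.")
  ut <- upper.tri(rdm_x, diag = FALSE)
  x <- rdm_x[ut]; y <- rdm_y[ut]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("too few defined upper-triangle entries.")
  r <- corr_safe(x, y)
  if (is.na(r)) abort("RDM upper triangle is constant; RSA undefined.")
  r
}

#' Noise-corrected RSA between a source and a noisy target animal
#'
#' In `animal_pair` mode both systems are recordings: per bootstrap, each is
#' split into half-trial averages and the score is
#' `RSA(s1A, s2B) / sqrt(SB(RSA(s1A, s2A)) * SB(RSA(s1B, s2B)))`, i.e. the
#' cross-system RSA corrected by both systems' Spearman-Brown-corrected RDM
#' reliabilities. In `model` mode the source is a deterministic
#' `stimuli x features` matrix whose mapping reliability is exactly 1, so the
#' denominator reduces to `sqrt(SB(RSA(s1B, s2B)))`. The identity mapping is
#' used throughout (RSA compares across stimuli, so unit counts may differ).
#' Bootstraps with non-positive reliability terms are excluded and counted.
#'
#' @param x_source A [population_recording()] (`animal_pair` mode) or numeric
#'   `stimuli x features` matrix (`model` mode).
#' @param target A [population_recording()].
#' @param half_plan A [split_half_plan()].
#' @param mode `"animal_pair"` or `"model"`; inferred from `x_source` when
#'   omitted.
#' @param method RDM dissimilarity passed to [compute_rdm()].
#' @return A [consistency_result()] whose single "unit" is the target animal
#'   (RSA yields one value per animal, not per neuron).
#' @export
noise_corrected_rsa <- function(x_source, target,
                                half_plan = split_half_plan(),
                                mode = c("animal_pair", "model"),
                                method = "correlation") {
  if (missing(mode)) {
    mode <- if (inherits(x_source, "population_recording")) "animal_pair" else "model"
  } else {
    mode <- match.arg(mode)
  }
  if (mode == "model") {
    feat <- check_matrix(x_source, "x_source")
    if (nrow(feat) != n_stimuli(target)) {
      abort("`x_source` rows must match the target's stimulus count.")
    }
    rdm_model <- compute_rdm(feat, method = method)
  } else if (!identical(x_source$stimulus_ids, target$stimulus_ids)) {
    abort("`x_source` and `target` must share the same stimulus set.")
  }

  vals <- numeric(half_plan$n_bootstraps)
  ok <- logical(half_plan$n_bootstraps)
  diag_rows <- vector("list", half_plan$n_bootstraps)
  for (b in seq_len(half_plan$n_bootstraps)) {
    bseed <- derive_seed(half_plan$seed, b)
    th <- split_trials(target, seed = bseed)
    rdm_t1 <- compute_rdm(th$s1, method = method)
    rdm_t2 <- compute_rdm(th$s2, method = method)
    tgt_rel <- rsa_score(rdm_t1, rdm_t2)
    if (mode == "animal_pair") {
      sh <- split_trials(x_source, seed = derive_seed(bseed, 17))
      rdm_s1 <- compute_rdm(sh$s1, method = method)
      rdm_s2 <- compute_rdm(sh$s2, method = method)
      src_rel <- rsa_score(rdm_s1, rdm_s2)
      num <- rsa_score(rdm_s1, rdm_t2)
    } else {
      src_rel <- 1
      num <- rsa_score(rdm_model, rdm_t2)
    }
    good <- is.finite(num) && src_rel > 0 && tgt_rel > 0
    denom <- sqrt(spearman_brown(pmin(src_rel, 1)) * spearman_brown(pmin(tgt_rel, 1)))
    vals[b] <- if (good) num / denom else NA_real_
    ok[b] <- good
    diag_rows[[b]] <- tibble(split = 1L, bootstrap = b,
                             mean_numerator = num,
                             mean_map_reliability = src_rel,
                             mean_target_reliability = tgt_rel,
                             n_excluded = as.integer(!good))
  }
  per_unit <- tibble(animal_id = target$animal_id, unit = 1L,
                     value = mean(vals[ok]),
                     n_valid = sum(ok), n_total = length(ok),
                     dropped = sum(ok) < length(ok) / 2)
  consistency_result(per_unit, diagnostics = bind_rows(diag_rows),
                     metadata = list(label = sprintf("RSA (%s) -> %s", mode, target$animal_id),
                                     mapping = "identity", mode = mode,
                                     n_bootstraps = half_plan$n_bootstraps))
}
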