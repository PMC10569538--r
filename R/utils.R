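#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise ungroup
#' @importFrom stats cor cov sd var median quantile lm coef prcomp rnorm runif
#' @importFrom stats predict setNames
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic substream seeds below 2^31, derived from a master seed.
derive_seed <- function(master, salt) {
  master <- as.double(master) %% 1e6
  salt <- as.double(salt)
  as.integer((master * 2039 + salt * 7919 + 1) %% 2147483647)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (stimuli x units).", name))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains undefined values.", name))
  x
}

# Pearson correlation between matched columns of two matrices.
# Returns NA for zero-variance columns instead of erroring.
corr_columns <- function(a, b) {
  stopifnot(ncol(a) == ncol(b), nrow(a) == nrow(b))
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  out <- ifelse(den > 0, num / den, NA_real_)
  unname(out)
}

# Correlation of two vectors, NA when either is constant.
corr_safe <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  cor(x, y)
}
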