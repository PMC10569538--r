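#' Convolutional layer specification
#'
#' A layer is a tuple (number of filters, filter size, stride, padding),
#' optionally followed by a 3 x 3 stride-2 max pool.
#'
#' @param n_filters,kernel,stride,padding Layer parameters (`kernel >= 1`,
#'   `stride >= 1`, `padding >= 0`).
#' @param pool Append a kernel-3 stride-2 max pool after this layer.
#' @return A `conv_spec`.
#' @export
conv_spec <- function(n_filters, kernel, stride, padding, pool = FALSE) {
  n_filters <- check_count(n_filters, "n_filters")
  kernel <- check_count(kernel, "kernel")
  stride <- check_count(stride, "stride")
  padding <- check_count(padding, "padding", min = 0)
  structure(list(n_filters = n_filters, kernel = kernel, stride = stride,
                 padding = padding, pool = isTRUE(pool)),
            class = "conv_spec")
}

#' Shallow multi-stream architecture configuration
#'
#' Declarative description of the shallow/intermediate/deep architecture
#' family: one shallow convolution (64, 11, 4, 2) followed by a stride-2 max
#' pool, `n_streams` parallel intermediate blocks of two convolutions
#' \[(192, 5, 1, 2) + pool, (384, 3, 1, 1)\], and one deep convolution per
#' stream — (256, 3, 1, 1) when fed from an intermediate block, (256, 3, 2, 0)
#' when fed directly from the shallow module. Deep outputs are concatenated
#' across streams along the channel dimension and enter a readout that
#' adaptively average-pools to 6 x 6, flattens, and applies a linear layer.
#' The longest convolutional path excluding the readout is 4 layers.
#'
#' @param n_streams Number of parallel streams: 1, 2 or 6 (other counts only
#'   with `allow_other_counts = TRUE`).
#' @param allow_other_counts Permit stream counts outside the canonical set.
#' @return A `streamnet_config`.
#' @export
build_streamnet_config <- function(n_streams, allow_other_counts = FALSE) {
  n_streams <- check_count(n_streams, "n_streams")
  if (!n_streams %in% c(1L, 2L, 6L) && !allow_other_counts) {
    abort("`n_streams` must be 1, 2 or 6 (set allow_other_counts = TRUE to extend).")
  }
  structure(list(
    n_streams = n_streams,
    shallow = conv_spec(64, 11, 4, 2, pool = TRUE),
    intermediate = list(conv_spec(192, 5, 1, 2, pool = TRUE),
                        conv_spec(384, 3, 1, 1)),
    deep_from_intermediate = conv_spec(256, 3, 1, 1),
    deep_from_shallow = conv_spec(256, 3, 2, 0),
    readout = list(pool_to = 6L, kind = "adaptive_average_pool + flatten + linear"),
    longest_path = 4L
  ), class = "streamnet_config")
}

#' @export
print.streamnet_config <- function(x, ...) {
  fmt <- function(cs) sprintf("(%d, %d, %d, %d)%s", cs$n_filters, cs$kernel,
                              cs$stride, cs$padding, if (cs$pool) " + pool" else "")
  cat(sprintf("<streamnet_config> %d stream(s)\n", x$n_streams))
  cat("  shallow:      ", fmt(x$shallow), "\n")
  cat("  intermediate: [", paste(vapply(x$intermediate, fmt, ""), collapse = ", "),
      sprintf("] x %d\n", x$n_streams))
  cat("  deep:         ", fmt(x$deep_from_intermediate), "(from intermediate)\n")
  cat("  readout:       adaptive average pool ->",
      sprintf("%d x %d, flatten, linear\n", x$readout$pool_to, x$readout$pool_to))
  invisible(x)
}

conv_out_size <- function(w, cs) {
  out <- (w + 2 * cs$padding - cs$kernel) %/% cs$stride + 1L
  if (out < 1) {
    abort(sprintf("layer (%d, %d, %d, %d) yields non-positive size from input %d.",
                  cs$n_filters, cs$kernel, cs$stride, cs$padding, w))
  }
  if (cs$pool) {
    out <- (out - 3L) %/% 2L + 1L
    if (out < 1) abort("max pool yields non-positive size.")
  }
  out
}

#' Spatial sizes and channel counts through a StreamNet configuration
#'
#' Applies the convolution arithmetic `floor((W + 2P - K) / S) + 1` (and
#' `floor((W - 3) / 2) + 1` for the stride-2 pools) module by module.
#'
#' @param config A [build_streamnet_config()] result.
#' @param input_side Input image side in pixels (default 64).
#' @return Tibble with `module`, `size` (spatial side) and `channels`
#'   (concatenated across streams for the deep module and readout).
#' @export
compute_feature_shapes <- function(config, input_side = 64) {
  input_side <- check_count(input_side, "input_side")
  s_shallow <- conv_out_size(input_side, config$shallow)
  s_int <- s_shallow
  for (cs in config$intermediate) s_int <- conv_out_size(s_int, cs)
  s_deep <- conv_out_size(s_int, config$deep_from_intermediate)
  n <- config$n_streams
  tibble(
    module = c("input", "shallow", "intermediate", "deep", "readout"),
    size = as.integer(c(input_side, s_shallow, s_int, s_deep, config$readout$pool_to)),
    channels = c(NA_integer_, config$shallow$n_filters,
                 config$intermediate[[2]]$n_filters * n,
                 config$deep_from_intermediate$n_filters * n,
                 config$deep_from_intermediate$n_filters * n))
}

# ---- minimal seeded forward pass (conv / relu / max pool / adaptive pool) ---

conv2d <- function(x, w, stride, padding) {
  # x: H x W x Cin; w: k x k x Cin x Cout
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  h <- dim(x)[1]; wd <- dim(x)[2]
  if (padding > 0) {
    xp <- array(0, c(h + 2 * padding, wd + 2 * padding, cin))
    xp[padding + seq_len(h), padding + seq_len(wd), ] <- x
    x <- xp; h <- dim(x)[1]; wd <- dim(x)[2]
  }
  ho <- (h - k) %/% stride + 1L
  wo <- (wd - k) %/% stride + 1L
  # im2col: rows = output positions (row-major over ho x wo), cols = patch
  ri <- (seq_len(ho) - 1L) * stride
  ci <- (seq_len(wo) - 1L) * stride
  patch <- matrix(0, ho * wo, k * k * cin)
  col <- 0L
  for (c_ in seq_len(cin)) {
    plane <- x[, , c_]
    for (dj in seq_len(k)) for (di in seq_len(k)) {
      col <- col + 1L
      patch[, col] <- plane[outer(ri + di, ci + dj, function(a, b) a + (b - 1L) * h)]
    }
  }
  wm <- matrix(w, k * k * cin, cout)
  out <- patch %*% wm
  array(out, c(ho, wo, cout))
}

relu <- function(x) pmax(x, 0)

max_pool <- function(x, k = 3L, stride = 2L) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cc <- dim(x)[3]
  ho <- (h - k) %/% stride + 1L
  wo <- (wd - k) %/% stride + 1L
  out <- array(-Inf, c(ho, wo, cc))
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    r <- (i - 1L) * stride + seq_len(k)
    cl <- (j - 1L) * stride + seq_len(k)
    out[i, j, ] <- apply(x[r, cl, , drop = FALSE], 3, max)
  }
  out
}

adaptive_avg_pool <- function(x, out_side) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cc <- dim(x)[3]
  out <- array(0, c(out_side, out_side, cc))
  for (i in seq_len(out_side)) for (j in seq_len(out_side)) {
    r <- (floor((i - 1) * h / out_side) + 1):ceiling(i * h / out_side)
    cl <- (floor((j - 1) * wd / out_side) + 1):ceiling(j * wd / out_side)
    out[i, j, ] <- apply(x[r, cl, , drop = FALSE], 3, mean)
  }
  out
}

init_conv_weights <- function(cs, cin, seed) {
  fan_in <- cs$kernel^2 * cin
  with_seed(seed, array(rnorm(cs$kernel^2 * cin * cs$n_filters, sd = sqrt(1 / fan_in)),
                        c(cs$kernel, cs$kernel, cin, cs$n_filters)))
}

#' Untrained StreamNet feature extraction
#'
#' Instantiates the configured architecture with seeded random weights
#' (centered Gaussian, `sd = sqrt(1 / fan_in)`) and runs the stimuli through
#' convolution / ReLU / max-pool stages, returning flattened per-module
#' activations as a feature set: `shallow`, `intermediate` and `deep`
#' (streams concatenated along channels), plus `avgpool` (the readout's
#' adaptive 6 x 6 average pool of the deep output). Deterministic per seed.
#'
#' @param config A [build_streamnet_config()] result.
#' @param images List of `H x W` or `H x W x C` numeric arrays, or a 4-D
#'   `n x H x W x C` array; all images must share a shape that yields valid
#'   activation sizes.
#' @param seed Seed for the weight draws.
#' @return A [model_feature_set()] with provenance `"untrained"`.
#' @export
extract_untrained_features <- function(config, images, seed = 1) {
  if (is.array(images) && length(dim(images)) == 4) {
    images <- lapply(seq_len(dim(images)[1]), function(i) {
      a <- images[i, , , , drop = FALSE]; dim(a) <- dim(images)[-1]; a
    })
  }
  if (!is.list(images) || !length(images)) abort("`images` must be a nonempty list or 4-D array.")
  images <- lapply(images, function(im) {
    if (is.matrix(im)) dim(im) <- c(dim(im), 1L)
    if (length(dim(im)) != 3) abort("each image must be H x W or H x W x C.")
    im
  })
  cin <- dim(images[[1]])[3]
  compute_feature_shapes(config, input_side = dim(images[[1]])[1])  # validates sizes

  w_shallow <- init_conv_weights(config$shallow, cin, derive_seed(seed, 1))
  w_int <- lapply(seq_len(config$n_streams), function(s) {
    list(init_conv_weights(config$intermediate[[1]], config$shallow$n_filters,
                           derive_seed(seed, 100 + s)),
         init_conv_weights(config$intermediate[[2]], config$intermediate[[1]]$n_filters,
                           derive_seed(seed, 200 + s)))
  })
  w_deep <- lapply(seq_len(config$n_streams), function(s) {
    init_conv_weights(config$deep_from_intermediate, config$intermediate[[2]]$n_filters,
                      derive_seed(seed, 300 + s))
  })

  feats <- lapply(images, function(im) {
    a <- relu(conv2d(im, w_shallow, config$shallow$stride, config$shallow$padding))
    if (config$shallow$pool) a <- max_pool(a)
    shallow <- a
    ints <- lapply(seq_len(config$n_streams), function(s) {
      b <- relu(conv2d(a, w_int[[s]][[1]], config$intermediate[[1]]$stride,
                       config$intermediate[[1]]$padding))
      if (config$intermediate[[1]]$pool) b <- max_pool(b)
      b <- relu(conv2d(b, w_int[[s]][[2]], config$intermediate[[2]]$stride,
                       config$intermediate[[2]]$padding))
      if (config$intermediate[[2]]$pool) b <- max_pool(b)
      b
    })
    deeps <- lapply(seq_len(config$n_streams), function(s) {
      relu(conv2d(ints[[s]], w_deep[[s]], config$deep_from_intermediate$stride,
                  config$deep_from_intermediate$padding))
    })
    deep <- abind3(deeps)
    list(shallow = as.numeric(shallow),
         intermediate = as.numeric(abind3(ints)),
         deep = as.numeric(deep),
         avgpool = as.numeric(adaptive_avg_pool(deep, config$readout$pool_to)))
  })
  layers <- lapply(c("shallow", "intermediate", "deep", "avgpool"), function(nm) {
    do.call(rbind, lapply(feats, `[[`, nm))
  })
  names(layers) <- c("shallow", "intermediate", "deep", "avgpool")
  model_feature_set(layers, provenance = "untrained")
}

# concatenate a list of H x W x C arrays along channels
abind3 <- function(lst) {
  if (length(lst) == 1) return(lst[[1]])
  d <- dim(lst[[1]])
  out <- array(0, c(d[1], d[2], sum(vapply(lst, function(a) dim(a)[3], integer(1)))))
  at <- 0L
  for (a in lst) {
    out[, , at + seq_len(dim(a)[3])] <- a
    at <- at + dim(a)[3]
  }
  out
}
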