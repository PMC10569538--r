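#' Stimulus image preprocessing for model feature extraction
#'
#' Applies the validation-time transform chain matched to a model's training
#' regime, ending at a 64-pixel shortest edge:
#' * `imagenet_trained`: shortest edge to 256 px, center crop to 224 x 224,
#'   resize to `target_resolution x target_resolution` (64 x 64 default);
#' * `cifar_trained`: shortest edge to `target_resolution` preserving aspect
#'   ratio (a 918 x 1174-proportioned stimulus becomes 64 x 81).
#'
#' Resizing uses bilinear interpolation (EBImage) and is deterministic and
#' idempotent at the target resolution.
#'
#' @param images A numeric matrix (`H x W`), a 3-D array (`H x W x C`), or a
#'   list of such arrays, values on any common scale.
#' @param source_regime `"imagenet_trained"` or `"cifar_trained"`.
#' @param target_resolution Final shortest-edge size in pixels (default 64).
#' @return The transformed image(s), same container shape as the input.
#' @export
preprocess_stimulus_images <- function(images,
                                       source_regime = c("imagenet_trained", "cifar_trained"),
                                       target_resolution = 64) {
  source_regime <- match.arg(source_regime)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("package EBImage is required for image preprocessing.")
  }
  if (is.list(images)) {
    return(lapply(images, preprocess_stimulus_images,
                  source_regime = source_regime,
                  target_resolution = target_resolution))
  }
  img <- images
  h <- dim(img)[1]; w <- dim(img)[2]
  if (source_regime == "imagenet_trained") {
    img <- resize_shortest_edge(img, 256)
    img <- center_crop(img, 224)
    img <- resize_hw(img, target_resolution, target_resolution)
  } else {
    img <- resize_shortest_edge(img, target_resolution)
  }
  img
}

resize_hw <- function(img, h, w) {
  if (dim(img)[1] == h && dim(img)[2] == w) return(img)
  out <- EBImage::resize(EBImage::Image(img), w = h, h = w)
  # EBImage's w/h follow its x/y convention: x = first array dim
  a <- EBImage::imageData(out)
  a
}

resize_shortest_edge <- function(img, target) {
  h <- dim(img)[1]; w <- dim(img)[2]
  # the longer edge truncates (a 918 x 1174 stimulus at 64 becomes 64 x 81)
  if (h <= w) {
    resize_hw(img, target, floor(w * target / h))
  } else {
    resize_hw(img, floor(h * target / w), target)
  }
}

center_crop <- function(img, size) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < size || w < size) abort("image is smaller than the crop window.")
  r0 <- floor((h - size) / 2)
  c0 <- floor((w - size) / 2)
  if (length(dim(img)) == 3) {
    img[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
  } else {
    img[r0 + seq_len(size), c0 + seq_len(size), drop = FALSE]
  }
}
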