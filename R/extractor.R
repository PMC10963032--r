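# Pluggable deterministic feature extractors for the readout model.
#
# The readout model is agnostic to the network providing its feature maps.
# The package bundles a fixed-weight Gabor filter bank as the default
# extractor, so that model fitting, MEI synthesis and in-silico probes run
# identically whether features come from the bundled bank or from an
# externally supplied convolutional network exported as kernels.

gabor_kernel <- function(size, theta_deg, sf_cpp, phase_deg, sigma) {
  half <- (size - 1) / 2
  gx <- matrix(rep(seq(-half, half), size), size, size)
  gy <- t(gx)
  th <- theta_deg * pi / 180
  u <- gx * cos(th) + gy * sin(th)
  env <- exp(-(gx^2 + gy^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * sf_cpp * u + phase_deg * pi / 180)
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

#' Fixed-weight Gabor-bank feature extractor
#'
#' A deterministic convolutional filter bank of Gabor kernels spanning
#' `n_orientations` orientations and `n_phases` phases at a single spatial
#' frequency, applied with a stride. Kernels are zero-mean and L2
#' normalized. The default rectification (ReLU) makes the feature maps
#' nonlinear in the pixels, which keeps the factorized readout
#' identifiable; `rectify = FALSE` gives a purely linear bank.
#'
#' @param input_dim image size `c(H, W)` in pixels
#' @param n_orientations number of orientation channels
#' @param n_phases number of phase channels per orientation
#' @param sf spatial frequency of the kernels, cycles per pixel
#' @param kernel_px kernel side length (odd)
#' @param stride convolution stride
#' @param rectify apply a ReLU after the convolution
#' @return an object of class `chc_extractor`
#' @export
gabor_bank_extractor <- function(input_dim = c(32, 32), n_orientations = 8,
                                 n_phases = 2, sf = 0.12, kernel_px = 11,
                                 stride = 2, rectify = TRUE) {
  thetas <- (seq_len(n_orientations) - 1) * 180 / n_orientations
  phases <- (seq_len(n_phases) - 1) * 90
  C <- n_orientations * n_phases
  kernels <- array(0, dim = c(kernel_px, kernel_px, C))
  meta <- data.frame(theta = rep(thetas, each = n_phases),
                     phase = rep(phases, n_orientations))
  for (cc in seq_len(C)) {
    kernels[, , cc] <- gabor_kernel(kernel_px, meta$theta[cc], sf,
                                    meta$phase[cc], sigma = kernel_px / 5)
  }
  oh <- (input_dim[1] - kernel_px) %/% stride + 1L
  ow <- (input_dim[2] - kernel_px) %/% stride + 1L
  structure(list(name = "gabor_bank", kernels = kernels, stride = stride,
                 rectify = rectify, input_dim = input_dim,
                 map_shape = c(oh, ow), n_channels = C, channel_meta = meta),
            class = "chc_extractor")
}

#' Identity feature extractor
#'
#' Passes pixels through unchanged (one channel, stride 1). Used for toy
#' instances where the readout model is exactly linear in the pixels.
#'
#' @param input_dim image size `c(H, W)`
#' @return an object of class `chc_extractor`
#' @export
identity_extractor <- function(input_dim = c(16, 16)) {
  structure(list(name = "identity",
                 kernels = array(1, dim = c(1, 1, 1)), stride = 1L,
                 rectify = FALSE, input_dim = input_dim,
                 map_shape = input_dim, n_channels = 1L,
                 channel_meta = NULL),
            class = "chc_extractor")
}

#' @export
print.chc_extractor <- function(x, ...) {
  cat(sprintf("<chc_extractor:%s> input %dx%d -> map %dx%d x %d channels%s\n",
              x$name, x$input_dim[1], x$input_dim[2], x$map_shape[1],
              x$map_shape[2], x$n_channels,
              if (x$rectify) " (rectified)" else ""))
  invisible(x)
}

#' Extract (batch-normalized) feature-map activations
#'
#' Runs the extractor on an image batch and normalizes each channel to
#' zero mean and unit variance over the batch (over images and feature-map
#' positions). Pass previously computed `stats` to reuse training-set
#' normalization, e.g. for held-out images or synthesized inputs.
#'
#' @param images array H x W x N (single images are promoted)
#' @param extractor a `chc_extractor`
#' @param normalize apply per-channel standardization
#' @param stats optional list `list(mu, sd)` of per-channel constants
#' @return array N x P x C with attributes `map_shape` and `stats`
#' @export
extract_features <- function(images, extractor, normalize = TRUE,
                             stats = NULL) {
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  if (!all(dim(images)[1:2] == extractor$input_dim))
    stop("image size does not match extractor input_dim")
  X <- conv_bank(images, extractor$kernels, extractor$stride)
  if (extractor$rectify) {
    ms <- attr(X, "map_shape")
    X <- pmax(X, 0)
    attr(X, "map_shape") <- ms
  }
  if (normalize) {
    C <- dim(X)[3]
    if (is.null(stats)) {
      mu <- apply(X, 3, mean)
      sd <- apply(X, 3, stats::sd)
      sd[sd == 0 | !is.finite(sd)] <- 1
      stats <- list(mu = mu, sd = sd)
    }
    for (cc in seq_len(C)) X[, , cc] <- (X[, , cc] - stats$mu[cc]) / stats$sd[cc]
  }
  attr(X, "stats") <- stats
  X
}

#' Gradient of a weighted feature sum with respect to input pixels
#'
#' Given per-position/per-channel weights on the *normalized* feature maps
#' of a single image, returns the gradient on the pixels (the
#' vector-Jacobian product through normalization, optional rectification
#' and the convolution).
#' @noRd
extractor_input_grad <- function(image, extractor, grad_pc, stats) {
  g <- grad_pc
  C <- extractor$n_channels
  for (cc in seq_len(C)) g[, cc] <- g[, cc] / stats$sd[cc]
  if (extractor$rectify) {
    raw <- conv_bank(array(image, dim = c(dim(image), 1L)),
                     extractor$kernels, extractor$stride)
    mask <- matrix(as.numeric(raw[1, , ] > 0), nrow = dim(raw)[2])
    g <- g * mask
  }
  conv_bank_vjp(g, extractor$kernels, extractor$stride, dim(image),
                extractor$map_shape)
}
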