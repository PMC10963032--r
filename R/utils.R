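# Internal numerical helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's RNG stream.
#' @noRd
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' 2-D cross-correlation with 'same' output and zero padding
#' @noRd
conv2_same <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- (kr - 1L) / 2L; pc <- (kc - 1L) / 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- matrix(0, nr + 2L * pr, nc + 2L * pc)
  xp[pr + seq_len(nr), pc + seq_len(nc)] <- x
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * xp[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  }
  out
}

# 3x3 discrete Laplacian used for the spatial-smoothness penalty.
laplacian_kernel <- function() {
  matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
}

#' Strided valid cross-correlation of an image batch with a filter bank
#'
#' `images`: array H x W x N; `kernels`: array kh x kw x C.
#' Returns array N x P x C where P = oh * ow (column-major over the
#' feature map), plus the spatial shape as an attribute.
#' @noRd
conv_bank <- function(images, kernels, stride = 1L) {
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  H <- dim(images)[1]; W <- dim(images)[2]; N <- dim(images)[3]
  kh <- dim(kernels)[1]; kw <- dim(kernels)[2]; C <- dim(kernels)[3]
  oh <- (H - kh) %/% stride + 1L
  ow <- (W - kw) %/% stride + 1L
  if (oh < 1L || ow < 1L) stop("kernel larger than image")
  r0 <- (seq_len(oh) - 1L) * stride
  c0 <- (seq_len(ow) - 1L) * stride
  P <- oh * ow
  # im2col: rows ordered (i, j, n) with i fastest, matching column-major maps
  M <- matrix(0, P * N, kh * kw)
  col <- 1L
  for (b in seq_len(kw)) {
    for (a in seq_len(kh)) {
      M[, col] <- as.vector(images[r0 + a, c0 + b, , drop = FALSE])
      col <- col + 1L
    }
  }
  K <- matrix(kernels, kh * kw, C)
  Fm <- M %*% K                      # (P*N) x C
  out <- array(Fm, dim = c(P, N, C))
  out <- aperm(out, c(2, 1, 3))      # N x P x C
  attr(out, "map_shape") <- c(oh, ow)
  attr(out, "stride") <- stride
  out
}

#' Vector-Jacobian product of `conv_bank` for a single image
#'
#' `grad_pc`: P x C gradient on the (raw, unnormalized) feature maps.
#' Returns the H x W gradient on the input image.
#' @noRd
conv_bank_vjp <- function(grad_pc, kernels, stride, img_dim, map_shape) {
  kh <- dim(kernels)[1]; kw <- dim(kernels)[2]; C <- dim(kernels)[3]
  oh <- map_shape[1]; ow <- map_shape[2]
  r0 <- (seq_len(oh) - 1L) * stride
  c0 <- (seq_len(ow) - 1L) * stride
  g <- matrix(0, img_dim[1], img_dim[2])
  G <- array(grad_pc, dim = c(oh, ow, C))
  for (b in seq_len(kw)) {
    for (a in seq_len(kh)) {
      w <- kernels[a, b, ]             # length C
      contrib <- matrix(0, oh, ow)
      for (cc in seq_len(C)) {
        if (w[cc] != 0) contrib <- contrib + w[cc] * G[, , cc]
      }
      g[r0 + a, c0 + b] <- g[r0 + a, c0 + b] + contrib
    }
  }
  g
}

#' Minimal Adam optimizer state
#' @noRd
adam_init <- function(par) {
  list(m = par * 0, v = par * 0, t = 0L)
}

#' @noRd
adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Permutation p-value with the (k+1)/(n+1) correction
#' @noRd
perm_pvalue <- function(k, n) (k + 1) / (n + 1)

#' Gaussian smoothing of a vector (reflected edges)
#' @noRd
smooth_gauss <- function(x, sd_frames) {
  if (sd_frames <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_frames))
  kern <- stats::dnorm(seq(-half, half), sd = sd_frames)
  kern <- kern / sum(kern)
  n <- length(x)
  xp <- c(rev(x[seq_len(min(half, n))]), x,
          rev(x[seq.int(max(1L, n - half + 1L), n)]))
  out <- stats::filter(xp, kern, sides = 2)
  as.numeric(out[half + seq_len(n)])
}

#' Clipped, smoothed bout process emulating mouse running speed
#'
#' Alternating stationary/running bouts with Gaussian jitter, smoothed and
#' clipped at zero, so that both <1 cm/s and >5 cm/s epochs occur.
#' @noRd
running_speed_process <- function(n_frames, frame_rate,
                                  mean_speed = 12,
                                  bout_s = 8, rest_s = 6,
                                  smooth_s = 0.6) {
  state <- numeric(n_frames)
  t <- 1L
  running <- stats::runif(1) < 0.5
  while (t <= n_frames) {
    len_s <- if (running) stats::rexp(1, 1 / bout_s) else stats::rexp(1, 1 / rest_s)
    len <- max(1L, round(len_s * frame_rate))
    idx <- t:min(n_frames, t + len - 1L)
    state[idx] <- if (running) mean_speed * stats::runif(1, 0.6, 1.6) else 0
    t <- t + len
    running <- !running
  }
  sp <- state + stats::rnorm(n_frames, sd = 1.2)
  sp <- smooth_gauss(sp, smooth_s * frame_rate)
  pmax(sp, 0)
}

#' Percentage of a count, as printed in summary text (rounded to integers)
#'
#' @param k numerator count
#' @param n denominator count
#' @param digits digits kept after the decimal point
#' @return `100 * k / n`, rounded to `digits`
#' @export
percent_of <- function(k, n, digits = 0) {
  stopifnot(n > 0, k >= 0)
  round(100 * k / n, digits)
}

#' Pearson correlation that tolerates zero-variance inputs
#' @noRd
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Convert a window in seconds to frame offsets (round half up)
#' @noRd
s_to_frames <- function(x, frame_rate) {
  floor(x * frame_rate + 0.5)
}
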