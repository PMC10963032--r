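# Most-exciting-input (MEI) synthesis and in-silico response probes.

model_activation <- function(model, image, neuron_set) {
  X <- extract_features(array(image, dim = c(dim(image), 1L)),
                        model$extractor, stats = model$norm_stats)
  sum(readout_predict_safe(model, X)[1, neuron_set])
}

# gradient of summed neuron-set activation wrt pixels
activation_grad <- function(model, image, neuron_set) {
  inc <- neuron_set[model$included[neuron_set]]
  if (length(inc) == 0) stop("neuron set contains no fitted neurons")
  Ws <- model$Ws[, inc, drop = FALSE]
  Wf <- model$Wf[, inc, drop = FALSE]
  # d(sum_n yhat_n)/dX[p,c] = sum_n Ws[p,n] Wf[c,n]
  G <- Ws %*% t(Wf)                   # P x C
  extractor_input_grad(image, model$extractor, G, model$norm_stats)
}

shift_image <- function(img, dx, dy) {
  out <- matrix(0, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Synthesize the most exciting input for a set of model neurons
#'
#' Gradient ascent on the pixels of the input image to maximize the summed
#' model response of `neuron_set` (a single neuron gives its MEI, several
#' give a composite MEI). Each step can apply a random integer jitter to
#' the image (a stochastic transformation discouraging pixel-locked
#' artefacts), and a high-frequency penalty (squared image Laplacian)
#' discourages high-frequency noise. Pixels are clipped to `[-1, 1]`
#' after every step. Optimization uses Adam with weight decay.
#'
#' @param model a `readout_model`
#' @param neuron_set indices of the neurons to drive (default neuron 1)
#' @param epochs ascent steps
#' @param lr Adam learning rate
#' @param weight_decay L2 pull of pixels toward gray
#' @param freq_lambda weight of the high-frequency penalty
#' @param jitter maximum absolute jitter in pixels per step (0 disables
#'   the stochastic transformation)
#' @param init_sd SD of the Gaussian noise init
#' @param seed RNG seed
#' @return an object of class `mei`: `image` (H x W in `[-1, 1]`),
#'   `activation`, `activation_trace` (activation of the untransformed
#'   image at each step), `opts`
#' @export
synthesize_mei <- function(model, neuron_set = 1L, epochs = 50, lr = 1e-2,
                           weight_decay = 1e-3, freq_lambda = 1e-3,
                           jitter = 2L, init_sd = 0.05, seed = 1) {
  dim_in <- model$extractor$input_dim
  L <- laplacian_kernel()
  local_seed(seed, {
    img <- matrix(stats::rnorm(prod(dim_in), sd = init_sd),
                  dim_in[1], dim_in[2])
    st <- adam_init(img)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      if (jitter > 0) {
        dx <- sample(-jitter:jitter, 1); dy <- sample(-jitter:jitter, 1)
        view <- shift_image(img, dx, dy)
      } else {
        dx <- dy <- 0L
        view <- img
      }
      g_act <- activation_grad(model, view, neuron_set)
      if (any(!is.finite(g_act))) stop("non-finite activation gradient")
      # un-shift the gradient back onto the image
      g_act <- shift_image(g_act, -dx, -dy)
      g_pen <- 2 * freq_lambda * conv2_same(conv2_same(img, L), L) +
        2 * weight_decay * img
      st <- adam_step(st, -g_act + g_pen, lr)
      img <- img - st$delta
      img[img > 1] <- 1; img[img < -1] <- -1
      trace[ep] <- model_activation(model, img, neuron_set)
    }
    structure(list(image = img, activation = trace[epochs],
                   activation_trace = trace,
                   opts = list(epochs = epochs, lr = lr,
                               weight_decay = weight_decay,
                               freq_lambda = freq_lambda, jitter = jitter,
                               seed = seed)),
              class = "mei")
  })
}

#' @export
print.mei <- function(x, ...) {
  cat(sprintf("<mei> %dx%d image, activation %.4g after %d steps\n",
              nrow(x$image), ncol(x$image), x$activation,
              x$opts$epochs))
  invisible(x)
}

#' Dominant orientation of an image via its Fourier spectrum
#'
#' Power-weighted circular mean of the spectral orientation on the
#' doubled-angle circle (degrees in [0, 180)), excluding the DC
#' component. Used to compare MEIs against generating Gabor
#' orientations; the weighted mean avoids the angular quantization of a
#' single spectral peak on small images.
#'
#' @param image numeric matrix
#' @return orientation in degrees
#' @export
image_orientation <- function(image) {
  n <- nrow(image); m <- ncol(image)
  P <- Mod(stats::fft(image - mean(image)))^2
  fx <- ifelse(seq_len(n) - 1 <= n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
  fy <- ifelse(seq_len(m) - 1 <= m / 2, seq_len(m) - 1, seq_len(m) - 1 - m)
  P[1, 1] <- 0
  FX <- matrix(fx, n, m); FY <- matrix(fy, m, n, byrow = TRUE)
  phi <- atan2(FY, FX)                  # spectral angle per component
  z <- sum(P * exp(2i * phi))
  (Arg(z) / 2 * 180 / pi) %% 180
}

make_grating <- function(dim_in, theta_deg, sf_cpp, phase_deg, contrast) {
  half_r <- (dim_in[1] - 1) / 2; half_c <- (dim_in[2] - 1) / 2
  gx <- matrix(rep(seq(-half_r, half_r), dim_in[2]), dim_in[1], dim_in[2])
  gy <- t(matrix(rep(seq(-half_c, half_c), dim_in[1]), dim_in[2],
                 dim_in[1]))
  th <- theta_deg * pi / 180
  u <- gx * cos(th) + gy * sin(th)
  contrast * sin(2 * pi * sf_cpp * u + phase_deg * pi / 180)
}

#' In-silico stimulus probes of a readout model
#'
#' Presents parametric gratings to the model and summarizes each neuron:
#'
#' * `orientation`: 8 orientations (22.5 degrees apart) x 5 spatial
#'   frequencies (0.02-0.08 cpd) x 2 phases; per-orientation responses are
#'   the maximum over SF and phase and the OSI is 1-CircVar on the doubled
#'   angles.
#' * `sf`: 12 spatial frequencies (0.01-0.6 cpd); the preferred SF is the
#'   one with the maximum response over orientations and phases.
#' * `contrast`: contrasts 0.05-1 at each neuron's best
#'   orientation/SF/phase; the contrast sensitivity is the slope of a
#'   least-squares line through response vs contrast.
#'
#' Spatial frequencies in cycles/degree are converted to cycles/pixel via
#' `deg_per_pixel`, the angular size of one input pixel.
#'
#' @param model a `readout_model`
#' @param probe one of `"orientation"`, `"sf"`, `"contrast"`
#' @param deg_per_pixel visual degrees per image pixel
#' @return list with a per-neuron metric vector (`osi`, `pref_sf` in cpd,
#'   or `contrast_slope`) and the underlying tuning table
#' @export
insilico_probe <- function(model, probe = c("orientation", "sf",
                                            "contrast"),
                           deg_per_pixel = 2) {
  probe <- match.arg(probe)
  dim_in <- model$extractor$input_dim
  n_neur <- ncol(model$Ws)
  respond <- function(th, sf_cpd, ph, ct) {
    img <- make_grating(dim_in, th, sf_cpd * deg_per_pixel, ph, ct)
    X <- extract_features(array(img, dim = c(dim_in, 1L)),
                          model$extractor, stats = model$norm_stats)
    readout_predict_safe(model, X)[1, ]
  }
  if (probe == "orientation") {
    oris <- seq(0, 157.5, by = 22.5)
    sfs <- seq(0.02, 0.08, length.out = 5)
    phases <- c(0, 90)
    resp <- array(NA_real_,
                  dim = c(length(oris), length(sfs), length(phases),
                          n_neur))
    for (i in seq_along(oris)) for (j in seq_along(sfs))
      for (k in seq_along(phases))
        resp[i, j, k, ] <- respond(oris[i], sfs[j], phases[k], 1)
    by_ori <- apply(resp, c(1, 4), max)       # orientations x neurons
    osi <- vapply(seq_len(n_neur), function(nn) {
      if (any(is.na(by_ori[, nn]))) return(NA_real_)
      suppressWarnings(
        circ_var_selectivity(by_ori[, nn], oris, mode = "orientation"))
    }, numeric(1))
    return(list(metric = osi, tuning = by_ori, orientations = oris))
  }
  if (probe == "sf") {
    sfs <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.1, 0.2, 0.3,
             0.4, 0.6)
    oris <- seq(0, 157.5, by = 22.5)
    phases <- c(0, 90)
    by_sf <- matrix(-Inf, length(sfs), n_neur)
    for (j in seq_along(sfs)) {
      acc <- matrix(-Inf, length(oris) * length(phases), n_neur)
      rr <- 1L
      for (i in seq_along(oris)) for (k in seq_along(phases)) {
        acc[rr, ] <- respond(oris[i], sfs[j], phases[k], 1)
        rr <- rr + 1L
      }
      by_sf[j, ] <- apply(acc, 2, max)
    }
    pref <- sfs[apply(by_sf, 2, which.max)]
    pref[colSums(is.na(by_sf)) > 0] <- NA_real_
    return(list(metric = pref, tuning = by_sf, sfs = sfs))
  }
  # contrast probe
  contrasts <- c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1)
  oris <- seq(0, 157.5, by = 22.5)
  sfs <- seq(0.02, 0.08, length.out = 5)
  phases <- c(0, 90)
  combos <- expand.grid(th = oris, sf = sfs, ph = phases)
  full <- matrix(NA_real_, nrow(combos), n_neur)
  for (i in seq_len(nrow(combos)))
    full[i, ] <- respond(combos$th[i], combos$sf[i], combos$ph[i], 1)
  best <- apply(full, 2, which.max)
  resp_ct <- matrix(NA_real_, length(contrasts), n_neur)
  for (nn in seq_len(n_neur)) {
    if (is.na(full[1, nn])) next
    bb <- combos[best[nn], ]
    for (ci in seq_along(contrasts))
      resp_ct[ci, nn] <- respond(bb$th, bb$sf, bb$ph, contrasts[ci])[nn]
  }
  slope <- vapply(seq_len(n_neur), function(nn) {
    if (any(is.na(resp_ct[, nn]))) return(NA_real_)
    stats::coef(stats::lm(resp_ct[, nn] ~ contrasts))[2]
  }, numeric(1))
  list(metric = unname(slope), tuning = resp_ct, contrasts = contrasts)
}

#' Receptive-field size from a spatial weight map
#'
#' Fits a 2-D Gaussian (amplitude, centre, axis SDs, offset) to `Ws` by
#' least squares and reports the full width at half maximum,
#' `2 sqrt(2 ln 2)` times the geometric mean of the two axis SDs,
#' converted from feature-map pixels to visual degrees. Maps wider than
#' `exclude_deg` are flagged excluded; degenerate (flat) maps are flagged
#' as failed fits.
#'
#' @param Ws spatial weight map (matrix, or a vector with `map_shape`)
#' @param deg_per_map_pixel visual degrees per feature-map pixel
#'   (image-pixel calibration times the extractor stride)
#' @param map_shape shape used when `Ws` is a vector
#' @param exclude_deg exclusion cutoff in degrees
#' @return list `fwhm_deg`, `sigma_px` (geometric-mean SD in map pixels),
#'   `centre`, `ok`, `excluded`
#' @export
rf_size <- function(Ws, deg_per_map_pixel = 4, map_shape = NULL,
                    exclude_deg = 40) {
  if (is.null(dim(Ws))) {
    stopifnot(!is.null(map_shape))
    Ws <- matrix(Ws, map_shape[1], map_shape[2])
  }
  if (stats::sd(Ws) == 0 || any(!is.finite(Ws))) {
    return(list(fwhm_deg = NA_real_, sigma_px = NA_real_, centre = NULL,
                ok = FALSE, excluded = NA))
  }
  A <- abs(Ws)
  nr <- nrow(Ws); nc <- ncol(Ws)
  gx <- matrix(rep(seq_len(nr), nc), nr, nc)
  gy <- t(matrix(rep(seq_len(nc), nr), nc, nr))
  w <- A / sum(A)
  x0 <- sum(w * gx); y0 <- sum(w * gy)
  sx0 <- sqrt(max(sum(w * (gx - x0)^2), 0.25))
  sy0 <- sqrt(max(sum(w * (gy - y0)^2), 0.25))
  peak <- Ws[which.max(A)]
  obj <- function(p) {
    mdl <- p[1] * exp(-((gx - p[2])^2 / (2 * p[5]^2) +
                          (gy - p[3])^2 / (2 * p[6]^2))) + p[4]
    sum((mdl - Ws)^2)
  }
  fit <- tryCatch(
    stats::optim(c(peak, x0, y0, 0, sx0, sy0), obj, method = "L-BFGS-B",
                 lower = c(-Inf, 0, 0, -Inf, 0.2, 0.2),
                 upper = c(Inf, nr + 1, nc + 1, Inf, 3 * nr, 3 * nc),
                 control = list(maxit = 500)),
    error = function(e) NULL)
  tss <- sum((Ws - mean(Ws))^2)
  # a usable fit explains at least half the map's variance; the optimizer
  # reporting a machine-precision line-search stall is fine
  if (is.null(fit) || abs(fit$par[1]) < 1e-12 || fit$value > 0.5 * tss) {
    return(list(fwhm_deg = NA_real_, sigma_px = NA_real_, centre = NULL,
                ok = FALSE, excluded = NA))
  }
  sig <- sqrt(fit$par[5] * fit$par[6])
  fwhm <- 2 * sqrt(2 * log(2)) * sig * deg_per_map_pixel
  list(fwhm_deg = fwhm, sigma_px = sig, centre = fit$par[2:3], ok = TRUE,
       excluded = fwhm > exclude_deg)
}
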