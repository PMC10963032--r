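# Factorized spatial x feature readout model.
#
# Each neuron's predicted response to an image is a spatial inner product
# of a learned 2-D weight map Ws with every channel of the extractor's
# feature maps, followed by an inner product of the resulting channel
# vector with learned feature weights Wf:
#
#   yhat_n = [ sum_xy Ws(n) * X_l ] . Wf(n)
#
# Ws and Wf for all neurons are optimized jointly by Adam on a squared
# error loss regularized by a Laplacian smoothness penalty on Ws, an L1
# penalty on Wf and an L2 penalty on both.

#' Predicted responses of a readout model
#'
#' @param model a `readout_model`
#' @param X features, N x P x C array from [extract_features()]
#' @return N x neurons matrix of predicted responses
#' @export
readout_predict <- function(model, X) {
  stopifnot(dim(X)[2] == nrow(model$Ws), dim(X)[3] == nrow(model$Wf))
  N <- dim(X)[1]; C <- dim(X)[3]
  yhat <- matrix(0, N, ncol(model$Ws))
  for (cc in seq_len(C)) {
    yhat <- yhat + (X[, , cc] %*% model$Ws) *
      matrix(model$Wf[cc, ], N, ncol(model$Ws), byrow = TRUE)
  }
  yhat
}

# forward pass keeping the per-channel spatial projections for gradients
readout_forward <- function(Ws, Wf, X) {
  N <- dim(X)[1]; C <- dim(X)[3]; n <- ncol(Ws)
  S <- array(0, dim = c(N, n, C))
  yhat <- matrix(0, N, n)
  for (cc in seq_len(C)) {
    S[, , cc] <- X[, , cc] %*% Ws
    yhat <- yhat + S[, , cc] * matrix(Wf[cc, ], N, n, byrow = TRUE)
  }
  list(yhat = yhat, S = S)
}

readout_penalties <- function(Ws, Wf, lambdas, map_shape) {
  L <- laplacian_kernel()
  lap <- 0
  if (lambdas$lambda_s > 0) {
    for (j in seq_len(ncol(Ws))) {
      wmap <- matrix(Ws[, j], map_shape[1], map_shape[2])
      lap <- lap + sum(conv2_same(wmap, L)^2)
    }
  }
  list(laplace = lambdas$lambda_s * lap,
       l1 = lambdas$lambda_f * sum(abs(Wf)),
       l2 = lambdas$lambda_2 * (sum(Ws^2) + sum(Wf^2)))
}

#' Loss components of a readout model on a batch
#'
#' Returns the squared prediction error, the Laplacian smoothness penalty
#' on `Ws` (3x3 kernel, zero-padded 'same' convolution), the L1 penalty on
#' `Wf`, the L2 penalty on both weight sets, and their total.
#'
#' @param model a `readout_model`
#' @param X features, N x P x C
#' @param y observed responses, N x neurons
#' @return named list `error`, `laplace`, `l1`, `l2`, `total`
#' @export
readout_loss <- function(model, X, y) {
  yhat <- readout_predict(model, X)
  pen <- readout_penalties(model$Ws, model$Wf, model$lambdas,
                           model$map_shape)
  err <- sum((yhat - y)^2)
  out <- list(error = err, laplace = pen$laplace, l1 = pen$l1, l2 = pen$l2,
              total = err + pen$laplace + pen$l1 + pen$l2)
  if (any(!vapply(out, is.finite, logical(1))))
    stop("non-finite loss term: ",
         paste(names(out)[!vapply(out, is.finite, logical(1))],
               collapse = ", "))
  out
}

readout_gradients <- function(Ws, Wf, X, y, lambdas, map_shape) {
  fwd <- readout_forward(Ws, Wf, X)
  r2 <- 2 * (fwd$yhat - y)            # N x n
  N <- dim(X)[1]; C <- dim(X)[3]; n <- ncol(Ws)
  gWs <- matrix(0, nrow(Ws), n)
  gWf <- matrix(0, C, n)
  for (cc in seq_len(C)) {
    gWf[cc, ] <- colSums(r2 * fwd$S[, , cc])
    gWs <- gWs + crossprod(X[, , cc], r2) *
      matrix(Wf[cc, ], nrow(Ws), n, byrow = TRUE)
  }
  if (lambdas$lambda_s > 0) {
    L <- laplacian_kernel()
    for (j in seq_len(n)) {
      wmap <- matrix(Ws[, j], map_shape[1], map_shape[2])
      gWs[, j] <- gWs[, j] +
        2 * lambdas$lambda_s * as.vector(conv2_same(conv2_same(wmap, L), L))
    }
  }
  gWf <- gWf + lambdas$lambda_f * sign(Wf) + 2 * lambdas$lambda_2 * Wf
  gWs <- gWs + 2 * lambdas$lambda_2 * Ws
  list(gWs = gWs, gWf = gWf, yhat = fwd$yhat)
}

#' Fit the factorized readout model
#'
#' Jointly optimizes the spatial maps `Ws` and feature weights `Wf` of all
#' neurons with Adam (default 600 epochs, batch size 128). The learning
#' rate decays by `decay_factor` at the epochs in `decay_at` and the
#' returned weights are the snapshot with the best validation correlation.
#' (`lr_schedule = "none"` disables the decay; both behaviours are kept
#' because schedule semantics are a free design choice.)
#'
#' @param responses N x neurons matrix of trial-averaged response
#'   amplitudes
#' @param images H x W x N array of training images
#' @param extractor a `chc_extractor`
#' @param lambdas list with `lambda_s`, `lambda_f`, `lambda_2`
#' @param lr Adam learning rate
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param val_frac fraction of images held out for snapshot selection
#' @param decay_at epochs at which the learning rate is divided
#' @param decay_factor learning-rate division factor
#' @param lr_schedule `"step"` (default) or `"none"`
#' @param oracle_r optional per-neuron oracle correlations; neurons with
#'   `oracle_r <= 0` are excluded from fitting (kept as NA columns)
#' @param seed RNG seed for init and batching
#' @param init_sd standard deviation of the Gaussian weight init
#' @return an object of class `readout_model` with fields `Ws` (P x n),
#'   `Wf` (C x n), `lambdas`, `map_shape`, `norm_stats`, `extractor`,
#'   `train_log` (loss and validation correlation per epoch), `included`
#' @export
fit_readout <- function(responses, images, extractor,
                        lambdas = list(lambda_s = 1e-3, lambda_f = 1e-3,
                                       lambda_2 = 1e-5),
                        lr = 0.02, epochs = 600, batch_size = 128,
                        val_frac = 0.2, decay_at = c(200, 400),
                        decay_factor = 3, lr_schedule = c("step", "none"),
                        oracle_r = NULL, seed = 1, init_sd = 0.01) {
  lr_schedule <- match.arg(lr_schedule)
  responses <- as.matrix(responses)
  N <- dim(images)[3]
  stopifnot(nrow(responses) == N)
  included <- rep(TRUE, ncol(responses))
  if (!is.null(oracle_r)) included <- oracle_r > 0
  y_all <- responses[, included, drop = FALSE]
  n <- ncol(y_all)
  X <- extract_features(images, extractor)
  stats <- attr(X, "stats")
  P <- dim(X)[2]; C <- dim(X)[3]
  local_seed(seed, {
    n_val <- max(1L, round(val_frac * N))
    val_idx <- sample.int(N, n_val)
    tr_idx <- setdiff(seq_len(N), val_idx)
    Ws <- matrix(stats::rnorm(P * n, sd = init_sd), P, n)
    Wf <- matrix(stats::rnorm(C * n, sd = init_sd), C, n)
    stWs <- adam_init(Ws); stWf <- adam_init(Wf)
    Xtr <- X[tr_idx, , , drop = FALSE]
    ytr <- y_all[tr_idx, , drop = FALSE]
    Xval <- X[val_idx, , , drop = FALSE]
    yval <- y_all[val_idx, , drop = FALSE]
    best <- list(score = -Inf, Ws = Ws, Wf = Wf)
    log_total <- numeric(epochs); log_val <- numeric(epochs)
    cur_lr <- lr
    for (ep in seq_len(epochs)) {
      if (lr_schedule == "step" && ep %in% (decay_at + 1L))
        cur_lr <- cur_lr / decay_factor
      ord <- sample.int(length(tr_idx))
      starts <- seq(1L, length(ord), by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        b <- ord[s:min(s + batch_size - 1L, length(ord))]
        g <- readout_gradients(Ws, Wf, Xtr[b, , , drop = FALSE],
                               ytr[b, , drop = FALSE], lambdas,
                               extractor$map_shape)
        if (any(!is.finite(g$gWs)) || any(!is.finite(g$gWf)))
          stop("training diverged: non-finite gradient at epoch ", ep)
        ep_loss <- ep_loss + sum((g$yhat - ytr[b, , drop = FALSE])^2)
        stWs <- adam_step(stWs, g$gWs, cur_lr); Ws <- Ws - stWs$delta
        stWf <- adam_step(stWf, g$gWf, cur_lr); Wf <- Wf - stWf$delta
      }
      pen <- readout_penalties(Ws, Wf, lambdas, extractor$map_shape)
      log_total[ep] <- ep_loss + pen$laplace + pen$l1 + pen$l2
      yv <- readout_forward(Ws, Wf, Xval)$yhat
      vr <- vapply(seq_len(n), function(j) safe_cor(yv[, j], yval[, j]),
                   numeric(1))
      log_val[ep] <- mean(vr, na.rm = TRUE)
      if (is.finite(log_val[ep]) && log_val[ep] > best$score)
        best <- list(score = log_val[ep], Ws = Ws, Wf = Wf)
    }
    Ws_out <- matrix(NA_real_, P, length(included))
    Wf_out <- matrix(NA_real_, C, length(included))
    Ws_out[, included] <- best$Ws
    Wf_out[, included] <- best$Wf
    structure(list(Ws = Ws_out, Wf = Wf_out, lambdas = lambdas,
                   map_shape = extractor$map_shape,
                   layer_id = extractor$name, norm_stats = stats,
                   extractor = extractor, included = included,
                   train_log = data.frame(epoch = seq_len(epochs),
                                          total = log_total,
                                          val_cor = log_val),
                   val_score = best$score),
              class = "readout_model")
  })
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf(
    "<readout_model> %d neurons, map %dx%d, %d channels (%s), val r=%.3f\n",
    ncol(x$Ws), x$map_shape[1], x$map_shape[2], nrow(x$Wf), x$layer_id,
    x$val_score))
  invisible(x)
}

#' Exhaustive hyperparameter grid search
#'
#' Fits the readout for every row of `grid` and returns the combination
#' with the highest mean correlation. Following the original selection
#' rule the default scores combinations on the training images;
#' `select = "val"` scores on the held-out split instead.
#'
#' @param responses N x neurons matrix
#' @param images H x W x N array
#' @param extractor a `chc_extractor`
#' @param grid data.frame with columns `lambda_s`, `lambda_f`, `lambda_2`
#'   (optionally `lr`)
#' @param select `"train"` or `"val"`
#' @param ... passed to [fit_readout()]
#' @param seed RNG seed (shared across combinations)
#' @return list with `best` (row of `grid`), `model` (refit at the best
#'   combination), and `table` (grid plus scores)
#' @export
grid_search_readout <- function(responses, images, extractor, grid,
                                select = c("train", "val"), seed = 1, ...) {
  select <- match.arg(select)
  grid <- as.data.frame(grid)
  scores <- numeric(nrow(grid))
  models <- vector("list", nrow(grid))
  X <- extract_features(images, extractor)
  for (i in seq_len(nrow(grid))) {
    lam <- list(lambda_s = grid$lambda_s[i], lambda_f = grid$lambda_f[i],
                lambda_2 = grid$lambda_2[i])
    args <- list(responses = responses, images = images,
                 extractor = extractor, lambdas = lam, seed = seed, ...)
    if (!is.null(grid$lr)) args$lr <- grid$lr[i]
    m <- do.call(fit_readout, args)
    if (select == "train") {
      yhat <- readout_predict(m, X)
      rr <- vapply(seq_len(ncol(yhat)),
                   function(j) safe_cor(yhat[, j], responses[, j]),
                   numeric(1))
      scores[i] <- mean(rr, na.rm = TRUE)
    } else {
      scores[i] <- m$val_score
    }
    models[[i]] <- m
  }
  best_i <- which.max(scores)
  out_tab <- cbind(grid, score = scores)
  list(best = grid[best_i, , drop = FALSE], model = models[[best_i]],
       table = out_tab)
}

#' Oracle correlation across stimulus repeats
#'
#' For each neuron, correlates the response vectors over images between
#' every pair of repeats and averages the pairwise correlations. The
#' oracle correlation upper-bounds achievable model performance.
#'
#' @param test_responses repeats x images x neurons array
#' @return numeric vector of per-neuron oracle correlations
#' @export
oracle_correlation <- function(test_responses) {
  stopifnot(length(dim(test_responses)) == 3)
  R <- dim(test_responses)[1]
  if (R < 2) stop("need at least two repeats")
  pairs <- utils::combn(R, 2)
  vapply(seq_len(dim(test_responses)[3]), function(nn) {
    rs <- vapply(seq_len(ncol(pairs)), function(pp) {
      safe_cor(test_responses[pairs[1, pp], , nn],
               test_responses[pairs[2, pp], , nn])
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
}

#' Held-out prediction correlation
#'
#' Correlates model predictions with recorded responses to test images
#' (typically the repeat-averaged responses to the held-out image set).
#'
#' @param model a `readout_model`
#' @param images_test H x W x N array of held-out images
#' @param responses_test N x neurons matrix of recorded responses
#' @return per-neuron correlation (NA for excluded neurons)
#' @export
cross_val_correlation <- function(model, images_test, responses_test) {
  X <- extract_features(images_test, model$extractor,
                        stats = model$norm_stats)
  yhat <- readout_predict_safe(model, X)
  vapply(seq_len(ncol(yhat)), function(j) {
    if (any(is.na(yhat[, j]))) return(NA_real_)
    safe_cor(yhat[, j], responses_test[, j])
  }, numeric(1))
}

# predict tolerating NA columns for excluded neurons
readout_predict_safe <- function(model, X) {
  out <- matrix(NA_real_, dim(X)[1], ncol(model$Ws))
  inc <- model$included
  if (any(inc)) {
    sub <- model
    sub$Ws <- model$Ws[, inc, drop = FALSE]
    sub$Wf <- model$Wf[, inc, drop = FALSE]
    out[, inc] <- readout_predict(sub, X)
  }
  out
}

#' Response strength (peak over baseline SD)
#'
#' The maximum of the trial-averaged time course divided by the standard
#' deviation of that time course in the 200 ms before stimulus onset.
#'
#' @param trial_tensor trials x time x neurons array from
#'   [event_triggered()]
#' @param frame_rate Hz
#' @return SNR per neuron
#' @export
response_strength <- function(trial_tensor, frame_rate) {
  tm <- attr(trial_tensor, "time")
  if (is.null(tm)) stop("tensor lacks a 'time' attribute")
  avg <- apply(trial_tensor, c(2, 3), mean)   # time x neurons
  pre <- tm >= -0.2 & tm < 0
  if (sum(pre) < 2) stop("need at least two samples in the 200 ms baseline")
  base_sd <- apply(avg[pre, , drop = FALSE], 2, stats::sd)
  if (any(base_sd == 0)) stop("zero-variance baseline; SNR undefined")
  apply(avg, 2, max) / base_sd
}
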