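# Readout model: feature extraction, prediction, loss terms, fitting,
# oracle and cross-validated correlations, response strength.

test_that("feature extraction matches hand convolution on a tiny case", {
  # 2-filter extractor on a 3x3 image, identity-style checks by hand
  ker <- array(0, dim = c(1, 1, 2))
  ker[1, 1, 1] <- 2; ker[1, 1, 2] <- -1
  ex <- structure(list(name = "toy", kernels = ker, stride = 1L,
                       rectify = FALSE, input_dim = c(3, 3),
                       map_shape = c(3, 3), n_channels = 2L),
                  class = "chc_extractor")
  img <- matrix(1:9, 3, 3)
  X <- extract_features(array(img, dim = c(3, 3, 1)), ex,
                        normalize = FALSE)
  expect_equal(X[1, , 1], as.numeric(2 * img))
  expect_equal(X[1, , 2], as.numeric(-img))
  # strided valid convolution against an explicit loop
  set.seed(20)
  k <- array(rnorm(3 * 3 * 1), dim = c(3, 3, 1))
  im <- matrix(rnorm(36), 6, 6)
  ex2 <- structure(list(name = "toy2", kernels = k, stride = 2L,
                        rectify = FALSE, input_dim = c(6, 6),
                        map_shape = c(2, 2), n_channels = 1L),
                   class = "chc_extractor")
  X2 <- extract_features(array(im, dim = c(6, 6, 1)), ex2,
                         normalize = FALSE)
  oracle <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    patch <- im[(2 * i - 1):(2 * i + 1), (2 * j - 1):(2 * j + 1)]
    oracle[i, j] <- sum(patch * k[, , 1])
  }
  expect_equal(matrix(X2[1, , 1], 2, 2), oracle, tolerance = 1e-12)
})

test_that("batch normalization zeroes channels and is deterministic", {
  ex <- gabor_bank_extractor()
  imgs <- make_images(8, seed = 21)
  X <- extract_features(imgs, ex)
  for (cc in c(1, 9, 16)) {
    expect_equal(mean(X[, , cc]), 0, tolerance = 1e-10)
    expect_equal(sd(as.numeric(X[, , cc])), 1, tolerance = 1e-6)
  }
  expect_identical(X, extract_features(imgs, ex))
  gray <- array(0, dim = c(32, 32, 4))
  Xg <- extract_features(gray, ex)
  expect_true(all(abs(Xg) < 1e-10))
})

test_that("prediction equals the triple-loop oracle and is bilinear", {
  set.seed(22)
  N <- 4; P <- 6; C <- 3; n <- 2
  X <- array(rnorm(N * P * C), dim = c(N, P, C))
  m <- list(Ws = matrix(rnorm(P * n), P, n),
            Wf = matrix(rnorm(C * n), C, n))
  yhat <- readout_predict(m, X)
  oracle <- matrix(0, N, n)
  for (i in 1:N) for (j in 1:n) for (p in 1:P) for (cc in 1:C)
    oracle[i, j] <- oracle[i, j] + m$Ws[p, j] * X[i, p, cc] * m$Wf[cc, j]
  expect_equal(yhat, oracle, tolerance = 1e-12)
  # Wf = 0 silences; one-hot Ws reads out a single pixel
  expect_equal(readout_predict(list(Ws = m$Ws, Wf = m$Wf * 0), X),
               matrix(0, N, n))
  ws1 <- matrix(0, P, 1); ws1[3, 1] <- 1
  m1 <- list(Ws = ws1, Wf = matrix(rnorm(C), C, 1))
  expect_equal(readout_predict(m1, X)[, 1],
               as.numeric(X[, 3, ] %*% m1$Wf), tolerance = 1e-12)
  # superposition in Ws and in Wf separately
  m2 <- list(Ws = matrix(rnorm(P * n), P, n), Wf = m$Wf)
  expect_equal(readout_predict(list(Ws = m$Ws + m2$Ws, Wf = m$Wf), X),
               yhat + readout_predict(m2, X), tolerance = 1e-10)
  m3 <- list(Ws = m$Ws, Wf = matrix(rnorm(C * n), C, n))
  expect_equal(readout_predict(list(Ws = m$Ws, Wf = m$Wf + m3$Wf), X),
               yhat + readout_predict(m3, X), tolerance = 1e-10)
})

test_that("loss terms match direct formula evaluation", {
  set.seed(23)
  P <- 9; C <- 2; n <- 3; N <- 5
  X <- array(rnorm(N * P * C), dim = c(N, P, C))
  lam <- list(lambda_s = 0.3, lambda_f = 0.7, lambda_2 = 0.11)
  m <- structure(list(Ws = matrix(rnorm(P * n), P, n),
                      Wf = matrix(rnorm(C * n), C, n),
                      lambdas = lam, map_shape = c(3, 3)),
                 class = "readout_model")
  y <- readout_predict(m, X) + matrix(rnorm(N * n), N, n)
  ls <- readout_loss(m, X, y)
  expect_equal(ls$error, sum((readout_predict(m, X) - y)^2))
  L <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
  lap <- 0
  for (j in 1:n) {
    wmap <- matrix(m$Ws[, j], 3, 3)
    wp <- matrix(0, 5, 5); wp[2:4, 2:4] <- wmap
    conv <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3)
      conv[a, b] <- sum(wp[a:(a + 2), b:(b + 2)] * L)
    lap <- lap + sum(conv^2)
  }
  expect_equal(ls$laplace, lam$lambda_s * lap, tolerance = 1e-12)
  expect_equal(ls$l1, lam$lambda_f * sum(abs(m$Wf)))
  expect_equal(ls$l2, lam$lambda_2 * (sum(m$Ws^2) + sum(m$Wf^2)))
  expect_equal(ls$total, ls$error + ls$laplace + ls$l1 + ls$l2)
  # perfect predictions zero the error; constant Ws has zero interior
  # Laplacian response
  expect_equal(readout_loss(m, X, readout_predict(m, X))$error, 0)
  mc <- m; mc$Ws <- matrix(1, P, n)
  wfull <- matrix(0, 5, 5); wfull[2:4, 2:4] <- 1
  expect_equal(sum(wfull[3, 3] * 4 - wfull[2, 3] - wfull[4, 3] -
                     wfull[3, 2] - wfull[3, 4]), 0)
})

test_that("training loss decreases on a convex toy instance", {
  # identity extractor, no regularization: joint least squares
  ex <- identity_extractor(c(6, 6))
  set.seed(24)
  imgs <- array(rnorm(6 * 6 * 60), dim = c(6, 6, 60))
  ws <- matrix(rnorm(36 * 2), 36, 2)
  wf <- matrix(1, 1, 2)
  X <- extract_features(imgs, ex)
  y <- readout_predict(list(Ws = ws, Wf = wf), X)
  m <- fit_readout(y, imgs, ex,
                   lambdas = list(lambda_s = 0, lambda_f = 0,
                                  lambda_2 = 0),
                   epochs = 200, lr = 0.05, lr_schedule = "none", seed = 1)
  tl <- m$train_log$total
  late <- mean(tail(tl, 10)); early <- mean(head(tl, 10))
  expect_lt(late, early / 10)
  # noiseless realizable: training correlation approaches 1
  yhat <- readout_predict(m, X)
  expect_gt(min(diag(cor(yhat, y))), 0.999)
})

test_that("strong Wf penalty drives the feature weights toward zero", {
  ex <- identity_extractor(c(4, 4))
  set.seed(25)
  imgs <- array(rnorm(4 * 4 * 40), dim = c(4, 4, 40))
  y <- matrix(rnorm(40 * 2), 40, 2)
  m <- fit_readout(y, imgs, ex,
                   lambdas = list(lambda_s = 0, lambda_f = 1e4,
                                  lambda_2 = 0),
                   epochs = 120, lr = 0.05, lr_schedule = "none", seed = 1)
  expect_lt(max(abs(m$Wf)), 0.02)
})

test_that("grid search returns the arg-max and is order invariant", {
  ex <- identity_extractor(c(4, 4))
  set.seed(26)
  imgs <- array(rnorm(4 * 4 * 50), dim = c(4, 4, 50))
  X <- extract_features(imgs, ex)
  y <- readout_predict(list(Ws = matrix(rnorm(16 * 2), 16, 2),
                            Wf = matrix(1, 1, 2)), X)
  grid <- data.frame(lambda_s = c(0, 0, 0), lambda_f = c(0, 10, 1000),
                     lambda_2 = 0)
  gs <- grid_search_readout(y, imgs, ex, grid, epochs = 60, lr = 0.05,
                            lr_schedule = "none", seed = 2)
  expect_equal(gs$best$lambda_f, 0)
  expect_equal(nrow(gs$table), 3)
  # single-point grid returns it; permuted order finds the same winner
  gs1 <- grid_search_readout(y, imgs, ex, grid[2, ], epochs = 20,
                             lr = 0.05, seed = 2)
  expect_equal(gs1$best$lambda_f, 10)
  gsp <- grid_search_readout(y, imgs, ex, grid[c(3, 1, 2), ], epochs = 60,
                             lr = 0.05, lr_schedule = "none", seed = 2)
  expect_equal(gsp$best$lambda_f, gs$best$lambda_f)
})

test_that("oracle correlation averages repeat-pair correlations", {
  set.seed(27)
  base <- matrix(rnorm(10 * 3), 10, 3)
  reps <- array(NA_real_, dim = c(3, 10, 3))
  for (r in 1:3) reps[r, , ] <- base + rnorm(30, sd = 0.5)
  oc <- oracle_correlation(reps)
  oracle <- vapply(1:3, function(nn) {
    mean(c(cor(reps[1, , nn], reps[2, , nn]),
           cor(reps[1, , nn], reps[3, , nn]),
           cor(reps[2, , nn], reps[3, , nn])))
  }, numeric(1))
  expect_equal(oc, oracle, tolerance = 1e-12)
  # identical repeats are perfectly reliable
  ident <- array(rep(base, each = 2), dim = c(2, 10, 3))
  expect_equal(oracle_correlation(ident), rep(1, 3))
  # independent noise gives near-zero reliability on average
  set.seed(28)
  noise <- array(rnorm(2 * 200 * 1), dim = c(2, 200, 1))
  expect_lt(abs(oracle_correlation(noise)), 0.2)
})

test_that("cross-validated correlation matches direct correlation", {
  ex <- gabor_bank_extractor()
  gt <- make_ground_truth(n_chc = 0, n_pyc = 3, seed = 29)
  imgs <- make_images(30, seed = 30)
  rr <- make_image_responses(gt, imgs, ex, noise_sd = 0, n_test = 10)
  m <- structure(list(Ws = gt$readout_ws, Wf = gt$readout_wf,
                      map_shape = c(11, 11), extractor = ex,
                      norm_stats = rr$stats, included = rep(TRUE, 3)),
                 class = "readout_model")
  obs <- apply(rr$test, c(2, 3), mean)
  cv <- cross_val_correlation(m, imgs[, , rr$test_idx], obs)
  # the ground-truth model predicts its own noiseless responses exactly
  expect_equal(cv, rep(1, 3), tolerance = 1e-8)
  # shuffled predictions decorrelate
  set.seed(31)
  shuf <- obs[sample(10), ]
  direct <- vapply(1:3, function(j) {
    X <- extract_features(imgs[, , rr$test_idx], ex, stats = rr$stats)
    cor(readout_predict(m, X)[, j], shuf[, j])
  }, numeric(1))
  expect_equal(cross_val_correlation(m, imgs[, , rr$test_idx], shuf),
               direct, tolerance = 1e-10)
})

test_that("response strength is peak over baseline SD", {
  fr <- 20
  tens <- array(0, dim = c(6, 30, 2))
  attr(tens, "time") <- (seq_len(30) - 11) / fr
  set.seed(32)
  tens[, 1:10, ] <- rnorm(6 * 10 * 2, sd = 1)
  tens[, 15, 1] <- 30; tens[, 15, 2] <- 12
  snr <- response_strength(tens, fr)
  avg <- apply(tens, c(2, 3), mean)
  pre <- attr(tens, "time") >= -0.2 & attr(tens, "time") < 0
  oracle <- apply(avg, 2, max) / apply(avg[pre, ], 2, sd)
  expect_equal(snr, oracle, tolerance = 1e-12)
  # zero-variance baseline is an error
  tens0 <- array(0, dim = c(2, 30, 1))
  attr(tens0, "time") <- (seq_len(30) - 11) / fr
  expect_error(response_strength(tens0, fr), "baseline")
})

test_that("receptive-field size follows the closed form on ideal maps", {
  shape <- c(21, 21)
  gx <- matrix(rep(1:21, 21), 21, 21); gy <- t(gx)
  for (sig in c(1.5, 3)) {
    Ws <- exp(-((gx - 11)^2 + (gy - 11)^2) / (2 * sig^2))
    rf <- rf_size(Ws, deg_per_map_pixel = 1)
    expect_true(rf$ok)
    expect_equal(rf$fwhm_deg, 2 * sqrt(2 * log(2)) * sig,
                 tolerance = 1e-3)
  }
  # anisotropic map with the same sigma product has the same FWHM
  Wa <- exp(-((gx - 11)^2 / (2 * 4.5) + (gy - 11)^2 / (2 * 2)))
  rfa <- rf_size(Wa, deg_per_map_pixel = 1)
  expect_equal(rfa$fwhm_deg, 2 * sqrt(2 * log(2)) * (4.5 * 2)^(1 / 4),
               tolerance = 1e-3)
  # flat maps fail; wide maps are flagged excluded
  expect_false(rf_size(matrix(1, 11, 11))$ok)
  wide <- exp(-((gx - 11)^2 + (gy - 11)^2) / (2 * 8^2))
  expect_true(rf_size(wide, deg_per_map_pixel = 4)$excluded)
})
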