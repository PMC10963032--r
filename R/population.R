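# Population statistics: lifetime sparseness, pairwise and behavioural
# correlations, and LDA image decoding with a subsample permutation test.

#' Lifetime sparseness of a response distribution
#'
#' `[1 - (sum R_i / N)^2 / (sum R_i^2 / N)] / [1 - 1/N]`, ranging from 0
#' (equal response to every stimulus) to 1 (response to a single
#' stimulus). Responses may be negative (baseline-corrected activity); the
#' statistic is applied as defined, with a warning when the summed
#' response is negative.
#'
#' @param R response vector over stimuli (or images x neurons matrix;
#'   sparsity is then computed per column)
#' @return sparsity in [0, 1]; `NA` with a warning for all-zero vectors
#' @export
sparsity <- function(R) {
  if (!is.null(dim(R))) return(apply(R, 2, sparsity))
  N <- length(R)
  if (N < 2) stop("need at least two stimuli")
  if (all(R == 0)) {
    warning("all-zero responses: sparsity undefined")
    return(NA_real_)
  }
  if (sum(R) < 0)
    warning("summed response is negative; sparsity may fall outside [0,1]")
  num <- (sum(R) / N)^2
  den <- sum(R^2) / N
  (1 - num / den) / (1 - 1 / N)
}

#' Mean pairwise correlation within a cell type
#'
#' Pearson correlation of frame-wise activity between every pair of
#' same-type cells, restricted to frames passing the behavioural-state
#' mask (default: stationary frames, running speed below 1 cm/s). Each
#' cell's value is the mean correlation with all other cells of its type.
#'
#' @param traces neurons x frames activity matrix
#' @param cell_type character vector per neuron
#' @param speed running speed per frame (cm/s); required for
#'   `state = "stationary"`
#' @param state `"stationary"` or `"all"`
#' @param threshold stationary speed threshold (cm/s)
#' @return per-neuron mean correlation (NA for singleton types)
#' @export
pairwise_correlations <- function(traces, cell_type, speed = NULL,
                                  state = c("stationary", "all"),
                                  threshold = 1) {
  state <- match.arg(state)
  traces <- as.matrix(traces)
  stopifnot(length(cell_type) == nrow(traces))
  if (state == "stationary") {
    if (is.null(speed)) stop("speed required for stationary state")
    mask <- speed < threshold
    if (sum(mask) < 3) stop("fewer than 3 stationary frames")
  } else {
    mask <- rep(TRUE, ncol(traces))
  }
  sub <- traces[, mask, drop = FALSE]
  out <- rep(NA_real_, nrow(traces))
  for (ct in unique(cell_type)) {
    idx <- which(cell_type == ct)
    if (length(idx) < 2) next
    cm <- suppressWarnings(stats::cor(t(sub[idx, , drop = FALSE])))
    diag(cm) <- NA
    out[idx] <- rowMeans(cm, na.rm = TRUE)
  }
  out
}

#' Correlation of activity with a behavioural covariate
#'
#' @param traces neurons x frames activity matrix
#' @param covariate per-frame covariate (running speed or pupil area)
#' @return Pearson r per neuron
#' @export
behavior_correlation <- function(traces, covariate) {
  traces <- as.matrix(traces)
  stopifnot(length(covariate) == ncol(traces))
  apply(traces, 1, function(x) safe_cor(x, covariate))
}

# Shrinkage estimate of the pooled within-class covariance.
# Ledoit-Wolf-style analytic shrinkage toward a scaled identity.
pooled_shrunk_cov <- function(X, classes) {
  p <- ncol(X)
  Z <- X
  for (cl in unique(classes)) {
    idx <- classes == cl
    Z[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                      colMeans(X[idx, , drop = FALSE]))
  }
  N <- nrow(Z)
  S <- crossprod(Z) / N
  tau <- mean(diag(S))
  target <- diag(tau, p)
  # shrinkage intensity (Ledoit & Wolf 2004 applied to centred residuals)
  z2 <- rowSums(Z^2)
  beta_num <- sum(z2^2) / N^2 - sum(S^2) / N
  delta <- sum((S - target)^2)
  gamma <- if (delta > 0) max(0, min(1, beta_num / delta)) else 1
  (1 - gamma) * S + gamma * target
}

train_lda <- function(X, y) {
  classes <- sort(unique(y))
  mu_raw <- vapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE]), numeric(ncol(X)))
  mu <- if (is.matrix(mu_raw)) t(mu_raw) else matrix(mu_raw, ncol = 1)
  Sg <- pooled_shrunk_cov(X, y)
  R <- chol(Sg)
  # discriminant: x' Sg^-1 mu_k - mu_k' Sg^-1 mu_k / 2 + log pi_k
  W <- backsolve(R, forwardsolve(t(R), t(mu)))   # p x K
  b <- -0.5 * colSums(t(mu) * W) +
    log(as.numeric(table(y)[as.character(classes)]) / length(y))
  list(classes = classes, W = W, b = b)
}

predict_lda <- function(fit, X) {
  scores <- X %*% fit$W + matrix(fit$b, nrow(X), length(fit$b),
                                 byrow = TRUE)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' LDA population decoding with repeated stratified splits
#'
#' Trains a linear discriminant decoder on a random 80% of trials
#' (stratified by class) and tests on the remaining 20%, repeated
#' `n_runs` times. The pooled within-class covariance is regularized by
#' analytic shrinkage toward a scaled identity, which keeps the decoder
#' defined when neurons outnumber trials.
#'
#' @param responses trials x neurons response matrix
#' @param labels class label per trial (e.g. image id)
#' @param train_frac fraction of each class used for training
#' @param n_runs number of random splits
#' @param seed RNG seed
#' @return object of class `decoding_result`: `accuracy_per_run`,
#'   `mean_accuracy`, `chance`
#' @export
lda_decode <- function(responses, labels, train_frac = 0.8, n_runs = 50,
                       seed = 1) {
  responses <- as.matrix(responses)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(responses))
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least two classes")
  counts <- table(labels)
  if (any(floor(counts * train_frac) < 1) || any(counts < 2))
    stop("every class needs at least one training and one test trial")
  local_seed(seed, {
    acc <- vapply(seq_len(n_runs), function(run) {
      tr <- unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        sample(idx, max(1L, floor(length(idx) * train_frac)))
      }))
      te <- setdiff(seq_along(labels), tr)
      fit <- train_lda(responses[tr, , drop = FALSE], labels[tr])
      mean(predict_lda(fit, responses[te, , drop = FALSE]) == labels[te])
    }, numeric(1))
    structure(list(accuracy_per_run = acc, mean_accuracy = mean(acc),
                   chance = 1 / length(classes)),
              class = "decoding_result")
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> mean accuracy %.3f (chance %.3f, %d runs)\n",
              x$mean_accuracy, x$chance, length(x$accuracy_per_run)))
  if (!is.null(x$p_value))
    cat(sprintf("  subsample permutation p = %.4g (%d iterations)\n",
                x$p_value, length(x$null_distribution)))
  invisible(x)
}

#' Subsample permutation test for a focal population's decoding accuracy
#'
#' Compares the decoding accuracy of a small focal population (all its
#' neurons) against a null distribution of accuracies from size-matched
#' random subsets of a larger reference population, each evaluated with
#' [lda_decode()]. The default one-tailed p-value asks whether the focal
#' accuracy is *lower* than the reference distribution (fraction of null
#' accuracies at or below the focal accuracy, with the (k+1)/(n+1)
#' correction).
#'
#' @param focal_responses trials x focal-neurons matrix
#' @param reference_responses trials x reference-neurons matrix (same
#'   trials/labels)
#' @param labels class label per trial
#' @param group_size neurons drawn per null iteration (defaults to the
#'   focal population size)
#' @param n_iter null iterations
#' @param n_runs decoding splits per iteration
#' @param tail `"lower"`, `"upper"` or `"two"`
#' @param seed RNG seed
#' @return `decoding_result` with `null_distribution` and `p_value`
#' @export
subsample_permutation <- function(focal_responses, reference_responses,
                                  labels, group_size = NULL, n_iter = 1000,
                                  n_runs = 50,
                                  tail = c("lower", "upper", "two"),
                                  seed = 1) {
  tail <- match.arg(tail)
  focal_responses <- as.matrix(focal_responses)
  reference_responses <- as.matrix(reference_responses)
  if (is.null(group_size)) group_size <- ncol(focal_responses)
  if (group_size > ncol(reference_responses))
    stop("reference pool smaller than group_size")
  focal <- lda_decode(focal_responses, labels, n_runs = n_runs, seed = seed)
  null <- local_seed(seed + 1L, {
    vapply(seq_len(n_iter), function(it) {
      cols <- sample.int(ncol(reference_responses), group_size)
      lda_decode(reference_responses[, cols, drop = FALSE], labels,
                 n_runs = n_runs,
                 seed = sample.int(.Machine$integer.max, 1))$mean_accuracy
    }, numeric(1))
  })
  k_low <- sum(null <= focal$mean_accuracy)
  k_high <- sum(null >= focal$mean_accuracy)
  p <- switch(tail,
              lower = perm_pvalue(k_low, n_iter),
              upper = perm_pvalue(k_high, n_iter),
              two = min(1, 2 * min(perm_pvalue(k_low, n_iter),
                                   perm_pvalue(k_high, n_iter))))
  focal$null_distribution <- null
  focal$p_value <- p
  focal$tail <- tail
  focal
}
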