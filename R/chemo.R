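# Chemogenetic-silencing analysis: locomotion-modulation curves and
# fits, the locomotion modulation index, the per-neuron circular-shift
# permutation test, and group comparisons of modulated fractions.

#' Locomotion-binned activity curve
#'
#' Averages activity over frames grouped by running speed: the first bin
#' holds exactly stationary frames (speed = 0); each following bin is the
#' half-open interval (lo, hi] so a frame at exactly 10 cm/s falls in the
#' 5-10 bin. Frames faster than the last edge (default 20 cm/s) are
#' dropped.
#'
#' @param trace activity per frame (one neuron), or neurons x frames
#' @param speed running speed per frame (cm/s)
#' @param edges upper edges of the running bins (cm/s)
#' @return vector (or matrix) of mean activity per bin, names give the
#'   bins; empty bins are NA
#' @export
locomotion_curve <- function(trace, speed, edges = c(5, 10, 15, 20)) {
  if (!is.null(dim(trace))) {
    out <- t(apply(trace, 1, locomotion_curve, speed = speed,
                   edges = edges))
    colnames(out) <- names(locomotion_curve(trace[1, ], speed, edges))
    return(out)
  }
  stopifnot(length(trace) == length(speed))
  lo <- c(0, edges[-length(edges)])
  labels <- c("0", paste0(lo, "-", edges))
  bin <- rep(NA_integer_, length(speed))
  bin[speed == 0] <- 1L
  for (b in seq_along(edges)) {
    bin[speed > lo[b] & speed <= edges[b]] <- b + 1L
  }
  out <- vapply(seq_len(length(edges) + 1L), function(b) {
    sel <- !is.na(bin) & bin == b
    if (!any(sel)) NA_real_ else mean(trace[sel])
  }, numeric(1))
  if (all(is.na(out))) warning("all frames outside the speed bins")
  stats::setNames(out, labels)
}

#' Linear fit of activity against running speed
#'
#' Ordinary least squares over all frames: `activity ~ speed`.
#'
#' @param trace activity per frame (one neuron)
#' @param speed running speed per frame
#' @return list `intercept`, `slope` (`slope` is NA with a warning when
#'   the speed is constant)
#' @export
locomotion_fit <- function(trace, speed) {
  stopifnot(length(trace) == length(speed))
  if (stats::sd(speed) == 0) {
    warning("constant running speed: slope undefined")
    return(list(intercept = mean(trace), slope = NA_real_))
  }
  cf <- stats::coef(stats::lm(trace ~ speed))
  list(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' Locomotion modulation index
#'
#' `LMI = (mean_run - mean_stat) / (mean_run + mean_stat)` with running
#' frames above and stationary frames below the speed threshold (default
#' 1 cm/s).
#'
#' @param trace activity per frame (one neuron), or neurons x frames
#' @param speed running speed per frame
#' @param thresh speed threshold, cm/s
#' @return LMI in [-1, 1] when both means are positive; NA (flagged by a
#'   warning) when the denominator is not positive or a state is absent
#' @export
lmi <- function(trace, speed, thresh = 1) {
  if (!is.null(dim(trace)))
    return(apply(trace, 1, lmi, speed = speed, thresh = thresh))
  run <- speed > thresh
  stat <- speed < thresh
  if (!any(run) || !any(stat)) {
    warning("missing running or stationary frames: LMI undefined")
    return(NA_real_)
  }
  m_run <- mean(trace[run])
  m_stat <- mean(trace[stat])
  if (m_run + m_stat <= 0) {
    warning("non-positive LMI denominator")
    return(NA_real_)
  }
  (m_run - m_stat) / (m_run + m_stat)
}

#' Circular-shift permutation test for a pre/post activity change
#'
#' Activity is averaged in `bin_frames`-frame bins (default 30, about 2 s
#' at 15.5 Hz). The null distribution is built within the pre session: the
#' binned pre trace is split in two halves and the half-means differenced,
#' repeating over all `n` circular shifts of the starting point. The
#' observed statistic compares the first halves of the pre and post
#' sessions; with `observed = "averaged"` (default) the inter-session
#' difference is likewise computed at every pre-session shift with a
#' freshly randomized post-session starting point and the differences are
#' averaged, while `observed = "single"` performs one comparison with a
#' single random post-session start. The two-tailed p-value is the
#' corrected fraction of null |differences| at or above the observed
#' |difference|.
#'
#' Note that the circular-shift null draws are mutually dependent (the
#' half-mean difference is a smooth function of the shift), which leaves
#' the null with few effective degrees of freedom; see the package
#' vignette for the calibration consequences.
#'
#' @param trace_pre activity per frame in the pre session (one neuron),
#'   or a neurons x frames matrix (then a vector of p-values is returned)
#' @param trace_post activity per frame in the post session
#' @param bin_frames frames per bin
#' @param observed `"averaged"` or `"single"` (see above)
#' @param seed RNG seed (used for the post-session split starts)
#' @return list `p`, `observed` (post minus pre, sign-carrying), `null`
#'   (signed null differences); for matrix input, a data.frame with
#'   columns `p` and `delta`
#' @export
salb_permutation_test <- function(trace_pre, trace_post, bin_frames = 30,
                                  observed = c("averaged", "single"),
                                  seed = 1) {
  observed <- match.arg(observed)
  if (!is.null(dim(trace_pre))) {
    stopifnot(nrow(trace_pre) == nrow(trace_post))
    res <- lapply(seq_len(nrow(trace_pre)), function(i)
      salb_permutation_test(trace_pre[i, ], trace_post[i, ], bin_frames,
                            observed = observed, seed = seed + i))
    return(data.frame(p = vapply(res, `[[`, numeric(1), "p"),
                      delta = vapply(res, `[[`, numeric(1), "observed")))
  }
  bin_means <- function(x) {
    nb <- length(x) %/% bin_frames
    if (nb < 2) stop("trace shorter than two bins")
    colMeans(matrix(x[seq_len(nb * bin_frames)], nrow = bin_frames))
  }
  pre <- bin_means(trace_pre)
  post <- bin_means(trace_post)
  n <- length(pre)
  half <- n %/% 2
  half_diff <- function(x, shift) {
    xs <- x[((seq_len(n) - 1L + shift) %% n) + 1L]
    mean(xs[seq_len(half)]) - mean(xs[(half + 1L):(2L * half)])
  }
  null <- vapply(seq_len(n) - 1L, function(s) half_diff(pre, s),
                 numeric(1))
  first_half <- function(x, shift) {
    xs <- x[((seq_len(length(x)) - 1L + shift) %% length(x)) + 1L]
    mean(xs[seq_len(length(x) %/% 2)])
  }
  obs <- local_seed(seed, {
    if (observed == "single") {
      s_post <- sample.int(length(post), 1) - 1L
      first_half(post, s_post) - first_half(pre, 0L)
    } else {
      mean(vapply(seq_len(n) - 1L, function(s) {
        s_post <- sample.int(length(post), 1) - 1L
        first_half(post, s_post) - first_half(pre, s)
      }, numeric(1)))
    }
  })
  k <- sum(abs(null) >= abs(obs))
  list(p = perm_pvalue(k, n), observed = obs, null = null)
}

#' Classify neurons by silencing effect and compare group fractions
#'
#' Neurons with permutation p below `alpha` are classed `up` or `down` by
#' the sign of their activity change, the rest `unchanged`.
#'
#' @param p_values per-neuron permutation p-values
#' @param deltas per-neuron activity change (post minus pre)
#' @param alpha significance level
#' @return list `class` (factor per neuron), `fractions` (named vector)
#' @export
classify_modulated <- function(p_values, deltas, alpha = 0.05) {
  stopifnot(length(p_values) == length(deltas))
  if (length(p_values) == 0) stop("empty group")
  cls <- rep("unchanged", length(p_values))
  cls[p_values < alpha & deltas > 0] <- "up"
  cls[p_values < alpha & deltas < 0] <- "down"
  cls <- factor(cls, levels = c("up", "down", "unchanged"))
  list(class = cls, fractions = table(cls) / length(cls))
}

#' Two-proportion chi-squared comparison of modulated fractions
#'
#' Compares the fraction of modulated neurons between two groups (e.g.
#' silenced vs control) with a chi-squared test on the 2x2 counts
#' (without continuity correction).
#'
#' @param k1,n1 modulated count and total in group 1
#' @param k2,n2 modulated count and total in group 2
#' @return `htest` from [stats::chisq.test()]
#' @export
compare_modulated_fractions <- function(k1, n1, k2, n2) {
  if (n1 == 0 || n2 == 0) stop("empty group")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  stats::chisq.test(tab, correct = FALSE)
}
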