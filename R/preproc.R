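# Fluorescence preprocessing: neuropil correction, moving-percentile
# delta-F/F, event-triggered extraction, baseline correction, z-scoring.

#' Neuropil correction
#'
#' Subtracts a scaled neuropil trace from the raw ROI fluorescence:
#' `F - factor * Fneu`, elementwise.
#'
#' @param F raw fluorescence (neurons x frames, or a vector)
#' @param Fneu neuropil fluorescence, same shape
#' @param factor neuropil subtraction factor (default 0.7)
#' @return corrected trace, same shape as `F`
#' @export
neuropil_correct <- function(F, Fneu, factor = 0.7) {
  if (!all(dim(as.matrix(F)) == dim(as.matrix(Fneu))))
    stop("F and Fneu shapes differ")
  F - factor * Fneu
}

#' Delta-F/F with a moving-percentile baseline
#'
#' `dFF = (F - F0) / F0` where `F0` is a running percentile (default the
#' 10th) over a moving window (default 5000 frames). The window is centred
#' on the current frame and truncated at the session edges; for traces
#' shorter than the window the baseline is constant and equals the
#' percentile of the whole trace. Percentiles use linear interpolation
#' (`stats::quantile` type 7).
#'
#' For long sessions the baseline is evaluated every `step` frames and
#' linearly interpolated in between; the percentile over thousands of
#' frames drifts far more slowly than that. `step = 1` computes the
#' exact per-frame moving percentile; the default uses `window / 100`
#' (so small windows are always exact).
#'
#' @param F fluorescence matrix (neurons x frames) or vector
#' @param window moving window length in frames
#' @param percentile baseline percentile in (0, 100)
#' @param step baseline evaluation stride in frames
#' @return delta-F/F, same shape as `F`
#' @export
compute_dff <- function(F, window = 5000, percentile = 10,
                        step = max(1L, window %/% 100L)) {
  if (window < 1) stop("window must be >= 1")
  if (step < 1) stop("step must be >= 1")
  vec_in <- is.null(dim(F))
  F <- as.matrix(F)
  if (vec_in) F <- matrix(F, nrow = 1)
  n <- ncol(F)
  F0 <- matrix(0, nrow(F), n)
  p <- percentile / 100
  half <- window %/% 2
  if (n <= window) {
    F0[] <- apply(F, 1, stats::quantile, probs = p, names = FALSE)
  } else {
    eval_at <- unique(c(seq(1L, n, by = step), n))
    lo <- pmax(1L, eval_at - half)
    hi <- pmin(n, eval_at + (window - half - 1L))
    lo <- pmin(lo, pmax(1L, hi - window + 1L))
    for (i in seq_len(nrow(F))) {
      x <- F[i, ]
      q <- vapply(seq_along(eval_at), function(k)
        stats::quantile(x[lo[k]:hi[k]], probs = p, names = FALSE),
        numeric(1))
      F0[i, ] <- if (length(eval_at) == 1L) q
      else stats::approx(eval_at, q, xout = seq_len(n))$y
    }
  }
  if (any(F0 <= 0)) stop("degenerate baseline: F0 <= 0; check raw traces")
  out <- (F - F0) / F0
  if (vec_in) out <- as.numeric(out)
  out
}

#' Event-triggered trace extraction
#'
#' Cuts a window around each event and stacks the snippets into a
#' trials x time x neurons array. Events whose window would extend past
#' either session edge are dropped; the number of dropped events is
#' reported via the `"dropped"` attribute (and a message).
#'
#' The returned array carries a `"time"` attribute: the time in seconds of
#' each sample relative to the event (the event frame is at t = 0).
#'
#' @param traces neurons x frames matrix (typically delta-F/F)
#' @param events event frames (0-based) or a `chc_events` table
#' @param pre_s window extent before the event, seconds (>= 0)
#' @param post_s window extent after the event, seconds (> 0)
#' @param frame_rate frame rate in Hz
#' @return trials x time x neurons array with attributes `time`, `dropped`,
#'   `kept` (indices of retained events)
#' @export
event_triggered <- function(traces, events, pre_s, post_s, frame_rate) {
  traces <- as.matrix(traces)
  if (inherits(events, "chc_events") || is.data.frame(events))
    events <- events$frame
  n <- ncol(traces)
  pre_f <- s_to_frames(pre_s, frame_rate)
  post_f <- s_to_frames(post_s, frame_rate)
  if (post_f < 1) stop("post_s window too short for the frame rate")
  ev1 <- as.integer(events) + 1L   # to 1-based
  ok <- (ev1 - pre_f) >= 1L & (ev1 + post_f - 1L) <= n
  dropped <- sum(!ok)
  if (dropped > 0)
    message(sprintf("event_triggered: dropped %d event(s) at session edges",
                    dropped))
  kept <- which(ok)
  ntime <- pre_f + post_f
  out <- array(NA_real_, dim = c(length(kept), ntime, nrow(traces)))
  for (k in seq_along(kept)) {
    idx <- (ev1[kept[k]] - pre_f):(ev1[kept[k]] + post_f - 1L)
    out[k, , ] <- t(traces[, idx, drop = FALSE])
  }
  attr(out, "time") <- (seq_len(ntime) - pre_f - 1L) / frame_rate
  attr(out, "dropped") <- dropped
  attr(out, "kept") <- kept
  out
}

#' Baseline-correct an event-triggered tensor
#'
#' Subtracts, per trial and neuron, the mean over samples before the event
#' (t < 0 on the tensor's `time` attribute).
#'
#' @param trial_tensor trials x time x neurons array from
#'   [event_triggered()]
#' @return corrected tensor (attributes preserved)
#' @export
baseline_correct <- function(trial_tensor) {
  tm <- attr(trial_tensor, "time")
  if (is.null(tm)) stop("tensor lacks a 'time' attribute")
  pre <- which(tm < 0)
  if (length(pre) == 0) stop("no pre-event samples to form a baseline")
  base <- apply(trial_tensor[, pre, , drop = FALSE], c(1, 3), mean)
  out <- sweep(trial_tensor, c(1, 3), base, "-")
  attributes(out) <- attributes(trial_tensor)
  out
}

#' Z-score traces per neuron
#'
#' Standardizes each neuron's trace over the whole session. Constant traces
#' map to all zeros with a warning.
#'
#' @param traces neurons x frames matrix or a vector
#' @return z-scored traces, same shape
#' @export
zscore_traces <- function(traces) {
  vec_in <- is.null(dim(traces))
  traces <- as.matrix(traces)
  if (vec_in) traces <- matrix(traces, nrow = 1)
  mu <- rowMeans(traces)
  sd <- apply(traces, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sprintf("%d constant trace(s) z-scored to zeros", sum(flat)))
    sd[flat] <- 1
  }
  out <- (traces - mu) / sd
  if (vec_in) out <- as.numeric(out)
  out
}
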