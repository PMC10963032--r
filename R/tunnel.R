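# Virtual-tunnel analyses: position binning, functional clustering of
# pyramidal cells, Bhattacharyya-distance separability, visuomotor
# mismatch correction, locomotion and visual-flow onsets.

#' Tunnel trials eligible for profile analyses
#'
#' Keeps trials whose visual section is completed within a duration limit
#' (time from trial start to reward, default 15 s) and, optionally, drops
#' trials containing visuomotor mismatch events.
#'
#' @param session a tunnel `chc_session` (with `trial` per frame)
#' @param events `chc_events` with `trial_start`, `reward` and `mismatch`
#'   rows
#' @param max_duration_s duration cutoff, seconds
#' @param drop_mismatch exclude mismatch-containing trials
#' @return list `kept` (trial ids), `excluded_slow`, `excluded_mismatch`
#' @export
filter_tunnel_trials <- function(session, events, max_duration_s = 15,
                                 drop_mismatch = TRUE) {
  starts <- events[events$type == "trial_start", ]
  rewards <- events[events$type == "reward", ]
  mism <- events[events$type == "mismatch", ]
  trials <- starts$value
  dur <- vapply(trials, function(tr) {
    s <- starts$frame[starts$value == tr][1]
    r <- rewards$frame[rewards$value == tr]
    if (length(r) == 0) return(Inf)
    (r[1] - s) / session$frame_rate
  }, numeric(1))
  slow <- trials[dur > max_duration_s]
  mm_trials <- if (nrow(mism) > 0) {
    unique(session$trial[mism$frame + 1L])
  } else integer(0)
  kept <- setdiff(trials, slow)
  if (drop_mismatch) kept <- setdiff(kept, mm_trials)
  list(kept = kept, excluded_slow = slow,
       excluded_mismatch = intersect(mm_trials, trials))
}

#' Position-binned activity profiles
#'
#' Divides the tunnel (default 0-100 cm) into `n_bins` bins of `bin_cm`
#' each, averages all frames falling in a bin within a trial, then
#' averages over trials.
#'
#' @param traces neurons x frames activity matrix
#' @param session tunnel `chc_session` providing `position`, `trial` and
#'   `section`
#' @param trials trial ids to include (e.g. from
#'   [filter_tunnel_trials()]); default all
#' @param n_bins number of position bins
#' @param bin_cm bin width in cm
#' @return neurons x n_bins profile matrix; empty bins are NA and flagged
#'   via the `"empty_bins"` attribute
#' @export
bin_by_position <- function(traces, session, trials = NULL, n_bins = 50,
                            bin_cm = 2) {
  traces <- as.matrix(traces)
  pos <- session$position
  if (is.null(pos)) stop("session has no position data")
  if (is.null(trials)) trials <- unique(stats::na.omit(session$trial))
  in_vis <- !is.na(pos) & session$section == "visual" &
    session$trial %in% trials
  bin_idx <- pmin(n_bins, floor(pos / bin_cm) + 1L)
  n_neur <- nrow(traces)
  acc <- array(NA_real_, dim = c(length(trials), n_bins, n_neur))
  for (ti in seq_along(trials)) {
    sel <- in_vis & session$trial == trials[ti]
    if (!any(sel)) next
    bi <- bin_idx[sel]
    tr <- traces[, sel, drop = FALSE]
    for (b in unique(bi)) {
      acc[ti, b, ] <- rowMeans(tr[, bi == b, drop = FALSE])
    }
  }
  prof <- apply(acc, c(3, 2), mean, na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  empty <- which(colSums(!is.na(prof)) == 0)
  attr(prof, "empty_bins") <- empty
  attr(prof, "bin_centers") <- (seq_len(n_bins) - 0.5) * bin_cm
  prof
}

#' Visual-section response score of a position profile
#'
#' Mean activity between 20 and 80 cm minus mean activity between 0 and
#' 20 cm.
#'
#' @param profile neurons x bins matrix from [bin_by_position()] (or a
#'   single profile vector)
#' @param bin_cm bin width in cm
#' @return scalar per neuron
#' @export
tunnel_visual_response <- function(profile, bin_cm = 2) {
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  centers <- attr(profile, "bin_centers")
  if (is.null(centers)) centers <- (seq_len(ncol(profile)) - 0.5) * bin_cm
  stim <- centers > 20 & centers < 80
  start <- centers < 20
  rowMeans(profile[, stim, drop = FALSE], na.rm = TRUE) -
    rowMeans(profile[, start, drop = FALSE], na.rm = TRUE)
}

#' Cluster pyramidal cells by visual-section profile
#'
#' Ward agglomerative clustering on z-scored position profiles with the
#' number of clusters chosen by maximum mean silhouette width over a
#' candidate range. Silhouette evaluation cannot test k = 1; pair this
#' with [bd_separability()] to assess whether the chosen split is better
#' than no split.
#'
#' @param profiles neurons x bins activity profiles
#' @param k_range candidate cluster counts
#' @param zscore standardize each profile first (default), so clustering
#'   follows profile shape rather than amplitude
#' @return list `labels`, `k`, `silhouette_by_k`, `hclust`
#' @export
cluster_pycs <- function(profiles, k_range = 2:6, zscore = TRUE) {
  profiles <- as.matrix(profiles)
  z <- if (zscore) zscore_traces(profiles) else profiles
  if (any(!is.finite(z))) {
    z[!is.finite(z)] <- 0
  }
  d <- stats::dist(z)
  if (min(d) == max(d) && max(d) == 0)
    stop("degenerate input: all profiles identical")
  hc <- stats::hclust(d, method = "ward.D2")
  k_range <- k_range[k_range < nrow(z)]
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    if (length(unique(lab)) < 2) return(NA_real_)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  k_best <- k_range[which.max(sil)]
  list(labels = stats::cutree(hc, k = k_best), k = k_best,
       silhouette_by_k = stats::setNames(sil, k_range), hclust = hc)
}

# Bhattacharyya distance between two samples on shared histogram bins.
bd_statistic <- function(x, y, breaks) {
  P <- tabulate(findInterval(x, breaks, all.inside = TRUE),
                nbins = length(breaks) - 1L)
  Q <- tabulate(findInterval(y, breaks, all.inside = TRUE),
                nbins = length(breaks) - 1L)
  bc <- sum(sqrt((P / sum(P)) * (Q / sum(Q))))
  -log(bc)
}

fd_breaks <- function(x, n_bins = NULL) {
  if (is.null(n_bins)) {
    h <- 2 * stats::IQR(x) * length(x)^(-1 / 3)
    n_bins <- if (h <= 0) ceiling(sqrt(length(x)))
    else max(2L, ceiling(diff(range(x)) / h))
  }
  seq(min(x), max(x), length.out = n_bins + 1L)
}

#' Cluster separability by Bhattacharyya distance with a permutation test
#'
#' Bins the per-neuron visual-response scores of two clusters on shared
#' histogram edges (Freedman-Diaconis bin count on the pooled scores by
#' default), computes `BD = -ln sum_i sqrt(P_i Q_i)` between the two
#' normalized histograms, and compares it with a null distribution
#' obtained by shuffling neurons between clusters (cluster sizes held
#' fixed). Disjoint supports give `BD = Inf`, which counts as larger than
#' any finite null value. The p-value is the corrected fraction of
#' shuffled BD values at or above the observed one.
#'
#' @param visual_scores per-neuron scalar (z-scored visual response)
#' @param labels cluster label per neuron (two or more clusters; BD is
#'   computed between the first two label levels)
#' @param n_bins histogram bin count (default: Freedman-Diaconis)
#' @param n_perm permutation iterations
#' @param seed RNG seed
#' @return object of class `cluster_separability`: `bd`, `null_bd`, `p`,
#'   `n_bins`, `labels`
#' @export
bd_separability <- function(visual_scores, labels, n_bins = NULL,
                            n_perm = 1000, seed = 1) {
  stopifnot(length(visual_scores) == length(labels))
  lev <- unique(labels)
  if (length(lev) < 2) stop("need at least two clusters")
  g1 <- visual_scores[labels == lev[1]]
  g2 <- visual_scores[labels == lev[2]]
  if (length(g1) == 0 || length(g2) == 0) stop("empty cluster")
  pooled <- c(g1, g2)
  breaks <- fd_breaks(pooled, n_bins)
  obs <- bd_statistic(g1, g2, breaks)
  n1 <- length(g1)
  null <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n1)
      bd_statistic(pooled[idx], pooled[-idx], breaks)
    }, numeric(1))
  })
  k <- sum(null >= obs)
  structure(list(bd = obs, null_bd = null,
                 p = perm_pvalue(k, n_perm),
                 n_bins = length(breaks) - 1L, labels = labels),
            class = "cluster_separability")
}

#' @export
print.cluster_separability <- function(x, ...) {
  cat(sprintf(
    "<cluster_separability> BD = %.4f (%d bins), permutation p = %.4g\n",
    x$bd, x$n_bins, x$p))
  invisible(x)
}

#' Location-corrected visuomotor mismatch responses
#'
#' For each mismatch event, control trials (without mismatch) are
#' repeatedly subsampled at the same position bin in the tunnel; the
#' average control trace over `n_resample` draws is subtracted from the
#' mismatch trace, the difference is baseline-corrected, and the response
#' is the corrected trace averaged over a post-onset window (default
#' 0.2-1.2 s). Events whose position bin is never visited by a control
#' trial are dropped with a warning.
#'
#' @param traces neurons x frames activity matrix
#' @param session tunnel `chc_session`
#' @param events `chc_events` including `mismatch` rows (value = position
#'   cm)
#' @param n_resample control resampling draws per event
#' @param window response window, seconds after onset
#' @param pre_s baseline extent, seconds
#' @param bin_cm position-bin granularity for location matching
#' @param seed RNG seed
#' @return list `amplitude` (per neuron, averaged over events),
#'   `per_event` (events x neurons), `dropped_events`
#' @export
mismatch_response <- function(traces, session, events, n_resample = 100,
                              window = c(0.2, 1.2), pre_s = 0.5,
                              bin_cm = 2, seed = 1) {
  traces <- as.matrix(traces)
  fr <- session$frame_rate
  mism <- events[events$type == "mismatch", , drop = FALSE]
  if (nrow(mism) == 0) stop("no mismatch events")
  mm_trials <- unique(session$trial[mism$frame + 1L])
  control_trials <- setdiff(unique(stats::na.omit(session$trial)),
                            mm_trials)
  pre_f <- s_to_frames(pre_s, fr)
  post_f <- s_to_frames(window[2] + 0.1, fr)
  n <- ncol(traces)
  bin_of <- function(p) floor(p / bin_cm)
  # first frame of each control trial in each position bin
  ctrl_frames <- list()
  for (tr in control_trials) {
    sel <- which(session$trial == tr & session$section == "visual")
    if (length(sel) == 0) next
    b <- bin_of(session$position[sel])
    first <- sel[!duplicated(b)]
    for (i in seq_along(first)) {
      key <- as.character(b[!duplicated(b)][i])
      ctrl_frames[[key]] <- c(ctrl_frames[[key]], first[i])
    }
  }
  snippet <- function(f1) {
    # f1 is 1-based event frame
    if (f1 - pre_f < 1 || f1 + post_f - 1 > n) return(NULL)
    t(traces[, (f1 - pre_f):(f1 + post_f - 1), drop = FALSE])
  }
  tm <- (seq_len(pre_f + post_f) - pre_f - 1) / fr
  win_sel <- tm >= window[1] & tm <= window[2]
  base_sel <- tm < 0
  per_event <- NULL
  dropped <- 0L
  local_seed(seed, {
    for (e in seq_len(nrow(mism))) {
      f1 <- mism$frame[e] + 1L
      key <- as.character(bin_of(session$position[f1]))
      pool <- ctrl_frames[[key]]
      pool <- pool[!is.na(pool)]
      real <- snippet(f1)
      if (is.null(real) || length(pool) == 0) {
        dropped <- dropped + 1L
        next
      }
      ctrl_acc <- 0
      for (r in seq_len(n_resample)) {
        ctrl_acc <- ctrl_acc + snippet(sample(pool, 1))
      }
      corrected <- real - ctrl_acc / n_resample
      corrected <- sweep(corrected, 2,
                         colMeans(corrected[base_sel, , drop = FALSE]))
      amp <- colMeans(corrected[win_sel, , drop = FALSE])
      per_event <- rbind(per_event, amp)
    }
  })
  if (dropped > 0)
    warning(sprintf("%d mismatch event(s) dropped (no matched control)",
                    dropped))
  if (is.null(per_event)) stop("no usable mismatch events")
  list(amplitude = colMeans(per_event), per_event = per_event,
       dropped_events = dropped)
}

#' Detect locomotion onsets
#'
#' A frame is an onset when the mean running speed is below the threshold
#' in the preceding interval (default 0.5 s) and above it over the
#' following interval (default 2 s). Only the first qualifying frame per
#' bout is returned. `restrict` can limit detection to a frame subset
#' (e.g. the non-visual section after reward).
#'
#' @param speed running speed per frame (cm/s)
#' @param frame_rate Hz
#' @param thresh speed threshold, cm/s
#' @param pre_s preceding interval, seconds
#' @param post_s following interval, seconds
#' @param restrict optional logical per frame; onsets only where TRUE
#' @return 0-based onset frames
#' @export
detect_locomotion_onsets <- function(speed, frame_rate, thresh = 5,
                                     pre_s = 0.5, post_s = 2,
                                     restrict = NULL) {
  n <- length(speed)
  pre_f <- s_to_frames(pre_s, frame_rate)
  post_f <- s_to_frames(post_s, frame_rate)
  cand <- (pre_f + 1L):(n - post_f)
  if (!is.null(restrict)) cand <- cand[restrict[cand]]
  cs <- cumsum(c(0, speed))
  pre_mean <- (cs[cand] - cs[cand - pre_f]) / pre_f
  post_mean <- (cs[cand + post_f] - cs[cand]) / post_f
  hits <- cand[pre_mean < thresh & post_mean > thresh]
  if (length(hits) == 0) return(integer(0))
  # keep the first frame of each bout (split runs separated by > post_s)
  keep <- c(TRUE, diff(hits) > post_f)
  hits[keep] - 1L
}

#' Visual-flow onset responses
#'
#' Baseline-corrected activity averaged over a window after trial onset
#' (default 0.5-2 s, past the stimulus-free first 20 cm of the tunnel).
#' `speed_range` optionally restricts to events whose onset speed lies in
#' a closed interval (used to match closed-loop mismatch events to
#' open-loop flow halts).
#'
#' @param traces neurons x frames activity matrix
#' @param onset_frames 0-based flow/trial onset frames
#' @param frame_rate Hz
#' @param window response window, seconds
#' @param pre_s baseline extent, seconds
#' @param speed per-frame running speed (required with `speed_range`)
#' @param speed_range closed interval of onset speeds to keep, cm/s
#' @return list `amplitude` (neurons), `per_event`, `kept_events`
#' @export
flow_onset_response <- function(traces, onset_frames, frame_rate,
                                window = c(0.5, 2), pre_s = 0.5,
                                speed = NULL, speed_range = NULL) {
  if (!is.null(speed_range)) {
    if (is.null(speed)) stop("speed required with speed_range")
    v <- speed[onset_frames + 1L]
    onset_frames <- onset_frames[v >= speed_range[1] & v <= speed_range[2]]
  }
  if (length(onset_frames) == 0) stop("no onset events after filtering")
  tens <- event_triggered(traces, onset_frames, pre_s = pre_s,
                          post_s = window[2] + 0.1,
                          frame_rate = frame_rate)
  tens <- baseline_correct(tens)
  tm <- attr(tens, "time")
  sel <- tm >= window[1] & tm <= window[2]
  per_event <- apply(tens[, sel, , drop = FALSE], c(1, 3), mean)
  list(amplitude = colMeans(per_event), per_event = per_event,
       kept_events = onset_frames[attr(tens, "kept")])
}

#' Correlation of each chandelier cell with the PyC clusters
#'
#' Pearson correlation between trial-averaged traces (visual and
#' non-visual sections combined) of every ChC and every clustered PyC,
#' averaged per ChC over the members of each cluster.
#'
#' @param chc_traces ChCs x timepoints matrix of averaged traces
#' @param pyc_traces PyCs x timepoints matrix (same time base)
#' @param pyc_labels cluster label per PyC
#' @return data.frame, one row per ChC, one column of mean r per cluster
#' @export
chc_cluster_correlation <- function(chc_traces, pyc_traces, pyc_labels) {
  chc_traces <- as.matrix(chc_traces)
  pyc_traces <- as.matrix(pyc_traces)
  stopifnot(ncol(chc_traces) == ncol(pyc_traces),
            nrow(pyc_traces) == length(pyc_labels))
  lev <- sort(unique(pyc_labels))
  out <- matrix(NA_real_, nrow(chc_traces), length(lev))
  for (i in seq_len(nrow(chc_traces))) {
    for (j in seq_along(lev)) {
      members <- which(pyc_labels == lev[j])
      rr <- vapply(members, function(m)
        safe_cor(chc_traces[i, ], pyc_traces[m, ]), numeric(1))
      out[i, j] <- mean(rr, na.rm = TRUE)
    }
  }
  out <- as.data.frame(out)
  names(out) <- paste0("r_cluster_", lev)
  out
}
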