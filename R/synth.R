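# Synthetic-session generators with known ground truth.
#
# Each generator is the generative inverse of a downstream analysis:
# passive grating sessions follow the circular-Gaussian tuning model,
# image responses follow the factorized readout model, tunnel sessions
# contain two pyramidal-cell clusters with opposite profiles plus
# mismatch/locomotion transients, and chemogenetic pairs apply a
# multiplicative silencing effect. A fixed seed fully determines every
# generated value.

#' Evaluate the single circular Gaussian tuning model
#'
#' `R(theta) = C + Rp * exp(-ang_ori(theta - theta_pref)^2 / (2 sigma^2))`
#' with angular differences wrapped to [0, 90] degrees.
#'
#' @param theta stimulus directions, degrees
#' @param C offset
#' @param Rp preferred-peak amplitude
#' @param theta_pref preferred orientation, degrees
#' @param sigma tuning width, degrees
#' @return model response at each `theta`
#' @export
tuning_curve_orientation <- function(theta, C, Rp, theta_pref, sigma) {
  ori_model(theta, c(C, Rp, theta_pref, sigma))
}

#' Evaluate the double circular Gaussian tuning model
#'
#' Adds a second peak of amplitude `Rn` opposite the preferred direction;
#' angular differences wrap to [0, 180] degrees.
#'
#' @inheritParams tuning_curve_orientation
#' @param Rn null-direction peak amplitude
#' @return model response at each `theta`
#' @export
tuning_curve_direction <- function(theta, C, Rp, Rn, theta_pref, sigma) {
  dir_model(theta, c(C, Rp, Rn, theta_pref, sigma))
}

# smooth spatial bump on the feature map for ground-truth Ws
gauss_map <- function(shape, cx, cy, sg) {
  gx <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1], shape[2])
  gy <- t(matrix(rep(seq_len(shape[2]), shape[1]), shape[2], shape[1]))
  exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sg^2))
}

#' Ground-truth parameters for synthetic sessions
#'
#' Draws per-neuron generative parameters: circular-Gaussian tuning
#' (preferred direction, width, amplitudes, offset), arousal coupling,
#' factorized-readout weights (smooth spatial bump `readout_ws`, sparse
#' channel weights `readout_wf`), tunnel cluster identity for pyramidal
#' cells, and a multiplicative silencing effect. Chandelier cells get
#' high, homogeneous arousal gains and broad (weakly selective) channel
#' weights; pyramidal cells get low arousal gains and channel weights
#' concentrated on a single orientation.
#'
#' @param n_chc number of chandelier cells
#' @param n_pyc number of layer 2/3 pyramidal cells
#' @param n_l5 number of layer 5 pyramidal cells
#' @param map_shape spatial shape of the readout feature map
#' @param n_channels extractor channel count
#' @param tuning_model `"direction"` (double Gaussian) or `"orientation"`
#' @param seed integer seed; fully determines the draw
#' @return object of class `ground_truth`
#' @export
make_ground_truth <- function(n_chc = 5, n_pyc = 40, n_l5 = 0,
                              map_shape = c(11, 11), n_channels = 16,
                              tuning_model = c("direction", "orientation"),
                              seed = 1) {
  tuning_model <- match.arg(tuning_model)
  n <- n_chc + n_pyc + n_l5
  stopifnot(n > 0)
  local_seed(seed, {
    cell_type <- c(rep("PyC", n_pyc), rep("ChC", n_chc),
                   rep("L5PyC", n_l5))
    is_chc <- cell_type == "ChC"
    P <- prod(map_shape)
    ws <- matrix(0, P, n)
    wf <- matrix(0, n_channels, n)
    n_ori_ch <- n_channels %/% 2      # bank layout: 2 phases per orientation
    for (i in seq_len(n)) {
      ws[, i] <- as.vector(gauss_map(map_shape,
                                     stats::runif(1, 3, map_shape[1] - 2),
                                     stats::runif(1, 3, map_shape[2] - 2),
                                     stats::runif(1, 1.2, 2.2)))
      ws[, i] <- ws[, i] / sqrt(sum(ws[, i]^2))
      if (is_chc[i]) {
        wf[, i] <- abs(stats::rnorm(n_channels, 0.5, 0.15))
      } else {
        ori <- sample.int(n_ori_ch, 1)
        ch <- (ori - 1L) * 2L + 1:2
        wf[ch, i] <- abs(stats::rnorm(2, 1, 0.2))
      }
    }
    cluster_id <- rep(NA_character_, n)
    if (n_pyc > 0) {
      half <- ceiling(n_pyc / 2)
      cluster_id[seq_len(n_pyc)] <- c(rep("V", half),
                                      rep("NV", n_pyc - half))
    }
    structure(list(
      n = n, cell_type = cell_type, cluster_id = cluster_id,
      preferred_direction = stats::runif(n, 0, 360),
      tuning_width_sigma = stats::runif(n, 15, 40),
      Rp = stats::runif(n, 0.6, 1.4),
      Rn = stats::runif(n, 0, 0.5) * ifelse(is_chc, 1, 0.6),
      C = stats::runif(n, 0, 0.08),
      arousal_gain = ifelse(is_chc, stats::runif(n, 0.8, 1.2),
                            pmax(0, stats::rnorm(n, 0.1, 0.15))),
      profile_gain = stats::runif(n, 0.6, 1.4),
      readout_ws = ws, readout_wf = wf,
      map_shape = map_shape, n_channels = n_channels,
      tuning_model = tuning_model,
      silencing_effect = rep(1, n),
      seed = seed), class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d neurons (%s), seed %d\n", x$n,
              paste(sprintf("%s=%d", names(table(x$cell_type)),
                            as.integer(table(x$cell_type))),
                    collapse = ", "), x$seed))
  invisible(x)
}

gt_tuning_response <- function(gt, i, theta) {
  if (gt$tuning_model == "orientation") {
    tuning_curve_orientation(theta, gt$C[i], gt$Rp[i],
                             gt$preferred_direction[i],
                             gt$tuning_width_sigma[i])
  } else {
    tuning_curve_direction(theta, gt$C[i], gt$Rp[i], gt$Rn[i],
                           gt$preferred_direction[i],
                           gt$tuning_width_sigma[i])
  }
}

wrap_session <- function(dff, gt, frame_rate, speed, pupil, f0 = 100,
                         position = NULL, trial = NULL, section = NULL) {
  if (any(dff <= -1)) stop("generated dff <= -1; cannot embed in F")
  new_session(F = f0 * (1 + dff), Fneu = matrix(0, nrow(dff), ncol(dff)),
              frame_rate = frame_rate, speed = speed, pupil = pupil,
              cell_type = gt$cell_type, position = position, trial = trial,
              section = section)
}

#' Synthetic passive grating session
#'
#' Generates a session of drifting-grating trials (8 directions, 45
#' degrees apart, shuffled order) whose noiseless trial responses follow
#' the ground-truth circular-Gaussian tuning model: each stimulus evokes
#' a boxcar of that amplitude from onset to 1.2 s. Running speed is a
#' clipped smoothed bout process, pupil area tracks it, and every
#' neuron's trace adds `arousal_gain * speed / 10` so arousal-coupled
#' neurons correlate positively with running. Fluorescence is embedded as
#' `F = f0 (1 + dFF)` with zero neuropil so the preprocessing chain
#' recovers the generated dFF.
#'
#' @param gt a `ground_truth`
#' @param n_trials_per_direction trials per direction
#' @param frame_rate Hz (the rig's effective rate is about 15.5)
#' @param noise_sd additive Gaussian noise on dFF per frame
#' @param stim_s stimulus duration, seconds
#' @param iti_s min/max inter-trial interval, seconds
#' @param running_fraction approximate fraction of time in running bouts
#' @param seed RNG seed (defaults to the ground-truth seed)
#' @return list `session` (a `chc_session`), `events` (grating onsets with
#'   direction and contrast)
#' @export
make_passive_session <- function(gt, n_trials_per_direction = 10,
                                 frame_rate = 15.5, noise_sd = 0.05,
                                 stim_s = 1, iti_s = c(4, 6),
                                 running_fraction = 0.2,
                                 seed = gt$seed) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  directions <- seq(0, 315, by = 45)
  local_seed(seed, {
    dirs <- sample(rep(directions, n_trials_per_direction))
    n_trials <- length(dirs)
    iti_f <- s_to_frames(stats::runif(n_trials, iti_s[1], iti_s[2]),
                         frame_rate)
    resp_f <- s_to_frames(1.2, frame_rate)
    onsets <- integer(n_trials)
    cur <- s_to_frames(2, frame_rate)
    for (k in seq_len(n_trials)) {
      onsets[k] <- cur
      cur <- cur + resp_f + iti_f[k]
    }
    n_frames <- cur + s_to_frames(2, frame_rate)
    bout_s <- 6
    rest_s <- bout_s * (1 - running_fraction) / max(running_fraction, 1e-6)
    speed <- running_speed_process(n_frames, frame_rate, bout_s = bout_s,
                                   rest_s = rest_s)
    pupil <- 800 + 40 * smooth_gauss(speed, frame_rate) +
      stats::rnorm(n_frames, sd = 5)
    pupil <- pmax(pupil, 1)
    dff <- matrix(0, gt$n, n_frames)
    for (i in seq_len(gt$n)) {
      tr <- numeric(n_frames)
      amps <- gt_tuning_response(gt, i, dirs)
      for (k in seq_len(n_trials)) {
        idx <- (onsets[k] + 1L):(onsets[k] + resp_f)
        tr[idx] <- tr[idx] + amps[k]
      }
      tr <- tr + gt$arousal_gain[i] * speed / 10
      if (noise_sd > 0) tr <- tr + stats::rnorm(n_frames, sd = noise_sd)
      dff[i, ] <- tr
    }
    events <- event_table(frame = onsets, type = "grating_on",
                          value = dirs, contrast = 1,
                          n_frames = n_frames)
    list(session = wrap_session(dff, gt, frame_rate, speed, pupil),
         events = events)
  })
}

#' Synthetic natural-like image set
#'
#' Pink-noise (1/f amplitude spectrum) backgrounds with 0-3 superimposed
#' oriented Gabor patches, standardized and clipped to [-1, 1]. Gives the
#' image set orientation and spatial-frequency structure without any
#' external data.
#'
#' @param n number of images
#' @param size image side length in pixels
#' @param max_gabors maximum Gabor patches per image
#' @param seed RNG seed
#' @return array `size x size x n`
#' @export
make_images <- function(n, size = 32, max_gabors = 3, seed = 1) {
  local_seed(seed, {
    fx <- ifelse(seq_len(size) - 1 <= size / 2, seq_len(size) - 1,
                 seq_len(size) - 1 - size)
    rad <- sqrt(outer(fx^2, fx^2, "+"))
    rad[1, 1] <- 1
    out <- array(0, dim = c(size, size, n))
    for (k in seq_len(n)) {
      ph <- stats::runif(size * size, 0, 2 * pi)
      spec <- (1 / rad) * exp(1i * matrix(ph, size, size))
      img <- Re(stats::fft(spec, inverse = TRUE)) / (size * size)
      img <- img / stats::sd(img) * 0.25
      for (g in seq_len(sample(0:max_gabors, 1))) {
        gk <- gabor_kernel(size = 2 * (size %/% 4) + 1,
                           theta_deg = stats::runif(1, 0, 180),
                           sf_cpp = stats::runif(1, 0.05, 0.2),
                           phase_deg = stats::runif(1, 0, 360),
                           sigma = stats::runif(1, 2, 5))
        r0 <- sample.int(size - nrow(gk) + 1L, 1)
        c0 <- sample.int(size - ncol(gk) + 1L, 1)
        amp <- stats::runif(1, 0.5, 1.5)
        rows <- r0:(r0 + nrow(gk) - 1L)
        cols <- c0:(c0 + ncol(gk) - 1L)
        img[rows, cols] <- img[rows, cols] + amp * gk /
          max(abs(gk))
      }
      img[img > 1] <- 1; img[img < -1] <- -1
      out[, , k] <- img
    }
    out
  })
}

#' Synthetic image responses from the ground-truth readout
#'
#' Noiseless responses are the factorized readout applied to the
#' ground-truth `readout_ws`/`readout_wf` on the extractor's normalized
#' features; Gaussian noise is added per presentation. The last `n_test`
#' images form a held-out set presented `repeats_per_test_image` times.
#'
#' @param gt a `ground_truth`
#' @param images array H x W x N from [make_images()]
#' @param extractor a `chc_extractor`; its feature geometry must match
#'   the ground-truth readout weights
#' @param repeats_per_test_image presentations of each test image
#' @param noise_sd Gaussian noise SD per presentation
#' @param n_test number of held-out test images
#' @param seed RNG seed
#' @return list `train` (train-images x neurons), `test` (repeats x
#'   test-images x neurons), `noiseless` (all images x neurons),
#'   `train_idx`, `test_idx`, `stats` (feature normalization constants)
#' @export
make_image_responses <- function(gt, images, extractor,
                                 repeats_per_test_image = 10,
                                 noise_sd = 0.05, n_test = 40,
                                 seed = gt$seed) {
  X <- extract_features(images, extractor)
  if (dim(X)[2] != nrow(gt$readout_ws) ||
      dim(X)[3] != nrow(gt$readout_wf))
    stop("extractor feature shape does not match ground-truth readout")
  model <- list(Ws = gt$readout_ws, Wf = gt$readout_wf)
  y0 <- readout_predict(model, X)
  N <- dim(images)[3]
  if (n_test >= N) stop("n_test must be smaller than the image count")
  test_idx <- (N - n_test + 1L):N
  train_idx <- seq_len(N - n_test)
  local_seed(seed, {
    train <- y0[train_idx, , drop = FALSE]
    if (noise_sd > 0)
      train <- train + matrix(stats::rnorm(length(train), sd = noise_sd),
                              nrow(train))
    test <- array(rep(y0[test_idx, , drop = FALSE],
                      each = repeats_per_test_image),
                  dim = c(repeats_per_test_image, n_test, gt$n))
    if (noise_sd > 0)
      test <- test + array(stats::rnorm(length(test), sd = noise_sd),
                           dim = dim(test))
    list(train = train, test = test, noiseless = y0,
         train_idx = train_idx, test_idx = test_idx,
         stats = attr(X, "stats"))
  })
}

# raised-cosine bump over [0, 1]
bump01 <- function(x) ifelse(x >= 0 & x <= 1, 0.5 - 0.5 * cos(2 * pi * x),
                             0)

#' Synthetic virtual-tunnel session
#'
#' Trials traverse a 1 m visual section (position integrated from a
#' smooth running-speed profile) followed by a 9 s non-visual section
#' with an auditory cue at 1 s and a reward at 3 s, a post-reward stop
#' and a fresh locomotion onset. Visually responsive pyramidal cells (V)
#' are active in the 20-80 cm stimulus zone; non-visual pyramidal cells
#' (NV) and chandelier cells are active at the tunnel start, in the
#' non-visual section, at locomotion onsets and at mismatch events.
#' Mismatch events are 0.5 s visual-flow halts inserted only between 20
#' and 80 cm while the animal runs, in a random subset of trials.
#'
#' `cluster_strength` scales the V-vs-NV profile difference: 0 gives
#' every pyramidal cell the same (average) profile, 1 the full opposite
#' profiles.
#'
#' @param gt a `ground_truth`
#' @param n_trials number of tunnel trials
#' @param mismatch_fraction fraction of trials with a mismatch event
#' @param frame_rate Hz
#' @param noise_sd Gaussian noise on dFF per frame
#' @param cluster_strength effect size of the V/NV profile separation
#' @param mismatch_amp peak dFF of the mismatch transient (NV/ChC)
#' @param onset_amp peak dFF of the locomotion-onset transient (NV/ChC)
#' @param seed RNG seed
#' @return list `session`, `events`
#' @export
make_tunnel_session <- function(gt, n_trials = 40, mismatch_fraction = 0.3,
                                frame_rate = 15.5, noise_sd = 0.05,
                                cluster_strength = 1, mismatch_amp = 1,
                                onset_amp = 1, seed = gt$seed) {
  if (mismatch_fraction < 0 || mismatch_fraction > 1)
    stop("mismatch_fraction must be in [0, 1]")
  local_seed(seed, {
    n_mm <- round(mismatch_fraction * n_trials)
    mm_trials <- if (n_mm > 0) sample.int(n_trials, n_mm) else integer(0)
    pos_l <- list(); spd_l <- list(); sec_l <- list(); tri_l <- list()
    ev <- list(frame = integer(0), type = character(0),
               value = numeric(0))
    onset_frames <- integer(0)
    mm_frames <- integer(0); mm_pos <- numeric(0)
    cur <- 0L
    nonvis_f <- s_to_frames(9, frame_rate)
    stop_at <- s_to_frames(3.5, frame_rate)   # stop shortly after reward
    go_at <- s_to_frames(6, frame_rate)       # fresh onset before next trial
    for (tr in seq_len(n_trials)) {
      # visual section: smooth running profile, position integrates speed
      v_speed <- numeric(0); v_pos <- numeric(0)
      p <- 0; base <- stats::runif(1, 16, 24)
      while (p < 100) {
        s <- max(5, base + 3 * sin(length(v_speed) / 10) +
                   stats::rnorm(1, sd = 1))
        p <- p + s / frame_rate
        v_speed <- c(v_speed, s); v_pos <- c(v_pos, min(p, 100))
      }
      nv <- length(v_speed)
      # non-visual section speed: run, stop after reward, restart
      n_speed <- numeric(nonvis_f)
      n_speed[seq_len(stop_at)] <-
        pmax(0, base + stats::rnorm(stop_at, sd = 1))
      n_speed[(stop_at + 1L):go_at] <- 0
      ramp <- seq(go_at + 1L, nonvis_f)
      n_speed[ramp] <- pmax(0, base * pmin(1, (ramp - go_at) / 3) +
                              stats::rnorm(length(ramp), sd = 1))
      ev$frame <- c(ev$frame, cur)
      ev$type <- c(ev$type, "trial_start"); ev$value <- c(ev$value, tr)
      if (tr %in% mm_trials) {
        cand <- which(v_pos > 20 & v_pos < 80 & v_speed > 5)
        if (length(cand) > 0) {
          f <- sample(cand, 1)
          mm_frames <- c(mm_frames, cur + f - 1L)
          mm_pos <- c(mm_pos, v_pos[f])
        }
      }
      ev$frame <- c(ev$frame, cur + nv)
      ev$type <- c(ev$type, "visual_exit"); ev$value <- c(ev$value, tr)
      ev$frame <- c(ev$frame, cur + nv + s_to_frames(1, frame_rate))
      ev$type <- c(ev$type, "cue"); ev$value <- c(ev$value, tr)
      ev$frame <- c(ev$frame, cur + nv + s_to_frames(3, frame_rate))
      ev$type <- c(ev$type, "reward"); ev$value <- c(ev$value, tr)
      onset_frames <- c(onset_frames, cur + nv + go_at)
      pos_l[[tr]] <- c(v_pos, rep(NA_real_, nonvis_f))
      spd_l[[tr]] <- c(v_speed, n_speed)
      sec_l[[tr]] <- c(rep("visual", nv), rep("nonvisual", nonvis_f))
      tri_l[[tr]] <- rep(tr, nv + nonvis_f)
      cur <- cur + nv + nonvis_f
    }
    position <- unlist(pos_l); speed <- unlist(spd_l)
    section <- unlist(sec_l); trial <- unlist(tri_l)
    n_frames <- length(speed)
    pupil <- 800 + 40 * smooth_gauss(speed, frame_rate) +
      stats::rnorm(n_frames, sd = 5)
    # per-frame profile drivers shared across neurons
    in_start <- !is.na(position) & position < 20
    in_stim <- !is.na(position) & position >= 20 & position <= 80
    in_nonvis <- section == "nonvisual"
    mm_kernel <- numeric(n_frames)
    tr_f <- s_to_frames(1, frame_rate)
    for (f in mm_frames) {
      idx <- (f + 1L):min(n_frames, f + tr_f)
      mm_kernel[idx] <- mm_kernel[idx] +
        bump01((seq_along(idx) - 1) / tr_f)
    }
    on_kernel <- numeric(n_frames)
    on_f <- s_to_frames(2, frame_rate)
    for (f in onset_frames) {
      idx <- (f + 1L):min(n_frames, f + on_f)
      on_kernel[idx] <- on_kernel[idx] +
        bump01((seq_along(idx) - 1) / on_f)
    }
    v_profile <- as.numeric(in_stim)
    nv_profile <- as.numeric(in_start) + 0.8 * as.numeric(in_nonvis)
    mean_profile <- (v_profile + nv_profile) / 2
    dff <- matrix(0, gt$n, n_frames)
    for (i in seq_len(gt$n)) {
      g <- gt$profile_gain[i]
      is_nv_like <- gt$cell_type[i] == "ChC" ||
        (!is.na(gt$cluster_id[i]) && gt$cluster_id[i] == "NV")
      own <- if (is_nv_like) nv_profile else v_profile
      s <- if (gt$cell_type[i] == "ChC") 1 else cluster_strength
      tr0 <- g * (s * own + (1 - s) * mean_profile)
      if (is_nv_like)
        tr0 <- tr0 + g * (mismatch_amp * mm_kernel +
                            onset_amp * on_kernel)
      if (noise_sd > 0) tr0 <- tr0 + stats::rnorm(n_frames, sd = noise_sd)
      dff[i, ] <- tr0
    }
    if (length(mm_frames) > 0) {
      ev$frame <- c(ev$frame, mm_frames)
      ev$type <- c(ev$type, rep("mismatch", length(mm_frames)))
      ev$value <- c(ev$value, mm_pos)
    }
    ord <- order(ev$frame)
    events <- event_table(frame = ev$frame[ord], type = ev$type[ord],
                          value = ev$value[ord], n_frames = n_frames)
    session <- wrap_session(dff, gt, frame_rate, speed, pmax(pupil, 1),
                            position = position, trial = trial,
                            section = section)
    list(session = session, events = events)
  })
}

#' Synthetic pre/post chemogenetic session pair
#'
#' Two gray-screen sessions with independently drawn but statistically
#' matched locomotion. Each neuron's activity is a positive baseline plus
#' arousal-coupled running modulation; in the post session the
#' (noiseless) activity is multiplied by that neuron's silencing effect.
#'
#' @param gt a `ground_truth`
#' @param silencing_effect per-neuron multiplicative factor for the post
#'   session (recycled; defaults to the ground-truth field)
#' @param session_length frames per session
#' @param frame_rate Hz
#' @param noise_sd Gaussian noise on dFF per frame
#' @param baseline added positive baseline dFF
#' @param seed RNG seed
#' @return list `pre`, `post` (both `chc_session`),
#'   `silencing_effect`
#' @export
make_chemo_pair <- function(gt, silencing_effect = gt$silencing_effect,
                            session_length = 9000, frame_rate = 15.5,
                            noise_sd = 0.05, baseline = 0.3,
                            seed = gt$seed) {
  eff <- rep_len(silencing_effect, gt$n)
  local_seed(seed, {
    make_one <- function(scale) {
      speed <- running_speed_process(session_length, frame_rate)
      pupil <- pmax(800 + 40 * smooth_gauss(speed, frame_rate) +
                      stats::rnorm(session_length, sd = 5), 1)
      dff <- matrix(0, gt$n, session_length)
      for (i in seq_len(gt$n)) {
        mu <- scale[i] * (baseline + gt$C[i] +
                            gt$arousal_gain[i] * speed / 10)
        dff[i, ] <- mu + if (noise_sd > 0)
          stats::rnorm(session_length, sd = noise_sd) else 0
      }
      wrap_session(dff, gt, frame_rate, speed, pupil)
    }
    list(pre = make_one(rep(1, gt$n)), post = make_one(eff),
         silencing_effect = eff)
  })
}
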