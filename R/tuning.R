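# Grating-response quantification and orientation/direction tuning.
#
# Mean responses to 8 drifting-grating directions are fit with single
# (orientation) or double (direction) circular Gaussians by nonlinear least
# squares, and tuning strength is quantified with 1-CircVar on the (doubled)
# angle circle.

# angular difference wrapped to [0, 90] (orientation)
ang_ori <- function(x) pmin(abs(x), abs(x - 180), abs(x + 180))

# angular difference wrapped to [0, 180] (direction)
ang_dir <- function(x) pmin(abs(x), abs(x - 360), abs(x + 360))

#' Per-trial grating response amplitudes
#'
#' For each stimulus onset, the response is the baseline-corrected
#' delta-F/F averaged over a post-onset window (default 0.2-1.2 s; the
#' baseline is the mean over t < 0 within `pre_s` of the onset).
#'
#' @param traces neurons x frames delta-F/F matrix
#' @param events `chc_events` with `grating_on` rows carrying direction in
#'   `value` and contrast in `contrast`
#' @param frame_rate Hz
#' @param window response window in seconds after onset
#' @param pre_s baseline extent before onset, seconds
#' @return list with `amplitude` (trials x neurons), `direction`,
#'   `contrast`, and `kept` (event rows retained)
#' @export
grating_response <- function(traces, events, frame_rate,
                             window = c(0.2, 1.2), pre_s = 0.5) {
  ev <- events[events$type == "grating_on", , drop = FALSE]
  tens <- event_triggered(traces, ev$frame, pre_s = pre_s,
                          post_s = window[2] + 0.1, frame_rate = frame_rate)
  tens <- baseline_correct(tens)
  tm <- attr(tens, "time")
  sel <- tm >= window[1] & tm <= window[2]
  amp <- apply(tens[, sel, , drop = FALSE], c(1, 3), mean)
  kept <- attr(tens, "kept")
  list(amplitude = amp, direction = ev$value[kept],
       contrast = ev$contrast[kept], kept = kept)
}

#' Exclude trials with running
#'
#' A trial is removed iff the running speed exceeds the threshold anywhere
#' from `window[1]` to `window[2]` seconds around stimulus onset
#' (default -1 s to +4 s, threshold 1 cm/s).
#'
#' @param event_frames 0-based stimulus onset frames
#' @param speed running speed per frame (cm/s)
#' @param frame_rate Hz
#' @param threshold speed threshold in cm/s
#' @param window seconds around onset to inspect
#' @return logical vector, `TRUE` for trials to keep
#' @export
exclude_running_trials <- function(event_frames, speed, frame_rate,
                                   threshold = 1, window = c(-1, 4)) {
  if (inherits(event_frames, "chc_events") || is.data.frame(event_frames))
    event_frames <- event_frames$frame
  n <- length(speed)
  lo <- s_to_frames(window[1], frame_rate)
  hi <- s_to_frames(window[2], frame_rate)
  vapply(as.integer(event_frames), function(f) {
    idx <- max(0L, f + lo):min(n - 1L, f + hi)
    !any(speed[idx + 1L] > threshold)
  }, logical(1))
}

#' Keep only high-contrast grating trials
#'
#' Tuning analyses include only gratings with contrast above a cutoff
#' (default 0.7).
#'
#' @param events a `chc_events` table
#' @param min_contrast contrast cutoff (exclusive)
#' @return the filtered event table
#' @export
filter_high_contrast <- function(events, min_contrast = 0.7) {
  keep <- events$type != "grating_on" |
    (!is.na(events$contrast) & events$contrast > min_contrast)
  events[keep, , drop = FALSE]
}

# single circular Gaussian (orientation)
ori_model <- function(theta, par) {
  par[1] + par[2] * exp(-ang_ori(theta - par[3])^2 / (2 * par[4]^2))
}

# double circular Gaussian (direction); par = (C, Rp, Rn, theta_pref, sigma)
dir_model <- function(theta, par) {
  par[1] +
    par[2] * exp(-ang_dir(theta - par[4])^2 / (2 * par[5]^2)) +
    par[3] * exp(-ang_dir(180 + theta - par[4])^2 / (2 * par[5]^2))
}

# Gauss-Newton refinement with a numerical Jacobian; polishes the best
# multi-start solution to machine precision where the fit is
# well-conditioned (gradient methods stall at SSE ~ 1e-11 there).
gn_polish <- function(par, responses, directions, model, lower, upper,
                      iters = 60) {
  sse <- function(p) sum((model(directions, p) - responses)^2)
  cur <- sse(par)
  np <- length(par)
  for (it in seq_len(iters)) {
    r <- model(directions, par) - responses
    J <- matrix(0, length(r), np)
    for (j in seq_len(np)) {
      h <- 1e-6 * max(1, abs(par[j]))
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      J[, j] <- (model(directions, pp) - model(directions, pm)) / (2 * h)
    }
    JtJ <- crossprod(J); Jtr <- crossprod(J, r)
    # Levenberg-Marquardt damping: grow until a step improves the SSE
    improved <- FALSE
    damp <- 1e-12 * max(diag(JtJ), 1)
    for (tries in 1:12) {
      step <- tryCatch(qr.solve(JtJ + diag(damp, np), Jtr),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        cand <- pmin(pmax(par - as.numeric(step), lower), upper)
        new <- sse(cand)
        if (is.finite(new) && new < cur) {
          par <- cand; cur <- new; improved <- TRUE
          break
        }
      }
      damp <- damp * 10
    }
    if (!improved || cur < 1e-26) break
  }
  list(par = par, value = cur)
}

fit_circular <- function(responses, directions, model, par_template,
                         sigma_bounds) {
  sse <- function(par) sum((model(directions, par) - responses)^2)
  best <- NULL
  r_rng <- diff(range(responses))
  for (th0 in directions) {
    par0 <- par_template(th0)
    lower <- rep(-Inf, length(par0)); upper <- rep(Inf, length(par0))
    lower[length(par0)] <- sigma_bounds[1]
    upper[length(par0)] <- sigma_bounds[2]
    fit <- tryCatch(
      stats::optim(par0, sse, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(list(par = NULL, sse = Inf, ok = FALSE))
  np <- length(best$par)
  lower <- rep(-Inf, np); upper <- rep(Inf, np)
  lower[np] <- sigma_bounds[1]; upper[np] <- sigma_bounds[2]
  pol <- gn_polish(best$par, responses, directions, model, lower, upper)
  if (pol$value <= best$value) {
    best$par <- pol$par; best$value <- pol$value
  }
  sig <- best$par[length(best$par)]
  pinned <- r_rng > 0 &&
    (abs(sig - sigma_bounds[1]) < 1e-6 || abs(sig - sigma_bounds[2]) < 1e-6)
  list(par = best$par, sse = best$value, ok = best$convergence == 0 && !pinned)
}

#' Fit a single circular Gaussian to orientation tuning
#'
#' Fits `R(theta) = C + Rp * exp(-ang_ori(theta - theta_pref)^2 / (2
#' sigma^2))` to the mean responses at the 8 stimulus directions by
#' nonlinear least squares, with a multi-start over the stimulus
#' directions for `theta_pref` and sigma bounded to `sigma_bounds`.
#' The selectivity field `osi` is 1-CircVar on the doubled angles (see
#' [circ_var_selectivity()]).
#'
#' @param responses mean response per direction
#' @param directions stimulus directions in degrees (default 0-315 in 45
#'   steps)
#' @param sigma_bounds allowed sigma range in degrees
#' @return list of class `tuning_fit` with `C`, `Rp`, `theta_pref`,
#'   `sigma`, `sse`, `fit_ok`, `osi`
#' @export
fit_orientation <- function(responses, directions = seq(0, 315, by = 45),
                            sigma_bounds = c(5, 90)) {
  stopifnot(length(responses) == length(directions))
  tmpl <- function(th0) c(min(responses),
                          max(responses) - min(responses), th0, 25)
  f <- fit_circular(responses, directions, ori_model, tmpl, sigma_bounds)
  if (!is.finite(f$sse) || is.null(f$par)) {
    return(structure(list(C = NA, Rp = NA, theta_pref = NA, sigma = NA,
                          sse = Inf, fit_ok = FALSE, osi = NA),
                     class = "tuning_fit"))
  }
  th <- f$par[3] %% 180
  structure(list(C = f$par[1], Rp = f$par[2], theta_pref = th,
                 sigma = f$par[4], sse = f$sse, fit_ok = f$ok,
                 osi = circ_var_selectivity(responses, directions,
                                            mode = "orientation")),
            class = "tuning_fit")
}

#' Fit a double circular Gaussian to direction tuning
#'
#' Adds a second peak 180 degrees opposite the preferred direction:
#' `R(theta) = C + Rp * exp(-ang_dir(theta - theta_pref)^2 / (2 sigma^2)) +
#' Rn * exp(-ang_dir(180 + theta - theta_pref)^2 / (2 sigma^2))`.
#' The selectivity field `dsi` is 1-CircVar on the raw angles.
#'
#' @inheritParams fit_orientation
#' @return list of class `tuning_fit` with `C`, `Rp`, `Rn`, `theta_pref`,
#'   `sigma`, `sse`, `fit_ok`, `dsi`
#' @export
fit_direction <- function(responses, directions = seq(0, 315, by = 45),
                          sigma_bounds = c(5, 90)) {
  stopifnot(length(responses) == length(directions))
  tmpl <- function(th0) c(min(responses),
                          max(responses) - min(responses),
                          (max(responses) - min(responses)) / 2, th0, 25)
  f <- fit_circular(responses, directions, dir_model, tmpl, sigma_bounds)
  if (!is.finite(f$sse) || is.null(f$par)) {
    return(structure(list(C = NA, Rp = NA, Rn = NA, theta_pref = NA,
                          sigma = NA, sse = Inf, fit_ok = FALSE, dsi = NA),
                     class = "tuning_fit"))
  }
  par <- f$par
  # identifiability: put the larger peak at theta_pref
  if (par[3] > par[2]) {
    par <- c(par[1], par[3], par[2], (par[4] + 180) %% 360, par[5])
  }
  structure(list(C = par[1], Rp = par[2], Rn = par[3],
                 theta_pref = par[4] %% 360, sigma = par[5], sse = f$sse,
                 fit_ok = f$ok,
                 dsi = circ_var_selectivity(responses, directions,
                                            mode = "direction")),
            class = "tuning_fit")
}

#' Tuning strength as 1-CircVar
#'
#' `|sum_k R(theta_k) e^{2 i theta_k}| / sum_k |R(theta_k)|` for
#' orientation (angle doubling) and `e^{i theta_k}` for direction.
#' Responses are normalized to their maximum first (largest response = 1;
#' ties broken by the lowest index) and negative means are rectified at
#' zero by default, so the result lies in [0, 1].
#'
#' @param responses mean response per direction
#' @param directions stimulus directions in degrees
#' @param mode `"orientation"` or `"direction"`
#' @param rectify clip negative responses at zero before the vector sum
#' @return selectivity in [0, 1]; `NA` (with a warning) when all responses
#'   are zero after rectification
#' @export
circ_var_selectivity <- function(responses, directions,
                                 mode = c("orientation", "direction"),
                                 rectify = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(responses) == length(directions))
  r <- responses
  if (rectify) r <- pmax(r, 0)
  mx <- max(r)
  if (mx == 0 || all(!is.finite(r))) {
    warning("all-zero responses: 1-CircVar undefined")
    return(NA_real_)
  }
  r <- r / mx
  mult <- if (mode == "orientation") 2 else 1
  th <- directions * pi / 180
  num <- Mod(sum(r * exp(1i * mult * th)))
  den <- sum(abs(r))
  num / den
}

#' Align tuning curves to the preferred direction
#'
#' Circularly shifts each neuron's tuning curve so that the stimulus
#' direction nearest its fitted preferred direction sits at the centre bin,
#' then averages across neurons.
#'
#' @param curves neurons x directions matrix of mean responses
#' @param theta_pref fitted preferred direction per neuron, degrees
#' @param directions stimulus directions in degrees
#' @return list with `aligned` (neurons x directions), `mean`, `sem`, and
#'   `rel_directions` (direction relative to preferred, centred at 0)
#' @export
align_tuning_curves <- function(curves, theta_pref,
                                directions = seq(0, 315, by = 45)) {
  curves <- as.matrix(curves)
  stopifnot(nrow(curves) == length(theta_pref),
            ncol(curves) == length(directions))
  nd <- length(directions)
  centre <- nd %/% 2 + 1L
  aligned <- matrix(NA_real_, nrow(curves), nd)
  for (i in seq_len(nrow(curves))) {
    d <- ang_dir(directions - theta_pref[i])
    pref_bin <- which.min(d)
    shift <- (pref_bin - centre) %% nd
    idx <- ((seq_len(nd) - 1L + shift) %% nd) + 1L
    aligned[i, ] <- curves[i, idx]
  }
  step <- diff(directions[1:2])
  list(aligned = aligned,
       mean = colMeans(aligned),
       sem = apply(aligned, 2, stats::sd) / sqrt(nrow(aligned)),
       rel_directions = (seq_len(nd) - centre) * step)
}

#' @export
print.tuning_fit <- function(x, ...) {
  flds <- vapply(x[!vapply(x, is.logical, logical(1))],
                 function(v) sprintf("%.3g", v), character(1))
  cat("<tuning_fit>", paste(names(flds), flds, sep = "=", collapse = " "),
      sprintf("fit_ok=%s\n", x$fit_ok))
  invisible(x)
}
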