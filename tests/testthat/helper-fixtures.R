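# Shared fixtures, generated in code at test time.

# small deterministic passive session with tuning but no arousal coupling
quiet_passive <- function(n_pyc = 4, seed = 11, noise_sd = 0,
                          tuning_model = "orientation", trials = 3) {
  gt <- make_ground_truth(n_chc = 0, n_pyc = n_pyc,
                          tuning_model = tuning_model, seed = seed)
  gt$arousal_gain[] <- 0
  list(gt = gt,
       out = make_passive_session(gt, n_trials_per_direction = trials,
                                  noise_sd = noise_sd, seed = seed + 1))
}

# direction grid used throughout
dirs8 <- seq(0, 315, by = 45)

# mean tuning curve per neuron from a session
session_tuning_curves <- function(session, events, neurons = NULL) {
  dff <- session$F / 100 - 1   # generator embeds dff as F = 100 (1 + dff)
  gr <- grating_response(dff, events, session$frame_rate)
  if (is.null(neurons)) neurons <- seq_len(ncol(gr$amplitude))
  t(vapply(neurons, function(i)
    as.numeric(tapply(gr$amplitude[, i], gr$direction, mean)),
    numeric(length(unique(gr$direction)))))
}

expect_angle_close <- function(got, want, tol, period = 360) {
  d <- abs(got - want) %% period
  expect_lt(min(d, period - d), tol)
}
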