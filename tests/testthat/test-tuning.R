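# Orientation/direction tuning: response amplitudes, trial exclusion,
# circular-Gaussian fits, 1-CircVar, curve alignment.

test_that("grating response amplitudes match an explicit slicing oracle", {
  set.seed(10)
  fr <- 10
  traces <- matrix(rnorm(2 * 300), 2, 300)
  ev <- event_table(frame = c(50, 150, 250), type = "grating_on",
                    value = c(0, 90, 180), contrast = 1)
  gr <- grating_response(traces, ev, fr, window = c(0.2, 1.2), pre_s = 0.5)
  # oracle: slice frames by hand (0-based events, window via round-half-up)
  for (k in 1:3) for (nn in 1:2) {
    on <- ev$frame[k] + 1
    base <- mean(traces[nn, (on - 5):(on - 1)])
    tm <- ((-5):12) / fr   # pre_f = 5, post_f = 13 -> samples -0.5..1.2 s
    seg <- traces[nn, (on - 5):(on + 12)] - base
    expect_equal(gr$amplitude[k, nn],
                 mean(seg[tm >= 0.2 & tm <= 1.2]), tolerance = 1e-12)
  }
  # flat trace gives 0; boxcar covering the window gives its height
  flat <- matrix(1, 1, 300)
  expect_equal(unname(grating_response(flat, ev, fr)$amplitude[, 1]),
               rep(0, 3))
})

test_that("running-trial exclusion follows the speed window rule", {
  fr <- 10
  speed <- rep(0, 400)
  # spike at +3.9 s after the second event must exclude it
  speed[201 + 39] <- 1.5
  keep <- exclude_running_trials(c(100, 200, 300), speed, fr)
  expect_equal(keep, c(TRUE, FALSE, TRUE))
  # hand-enumerated mixed set: any speed > 1 within [-1, 4] s excludes
  speed2 <- rep(0, 400)
  speed2[100 - 10 + 1] <- 2      # exactly -1 s for event at frame 99
  speed2[305] <- 0.9             # sub-threshold never excludes
  keep2 <- exclude_running_trials(c(99, 200, 300), speed2, fr)
  expect_equal(keep2, c(FALSE, TRUE, TRUE))
  expect_true(all(exclude_running_trials(c(50, 150), rep(0, 400), fr)))
})

test_that("high-contrast filter keeps only contrasts above 0.7", {
  ev <- event_table(frame = c(10, 20, 30, 40),
                    type = "grating_on", value = c(0, 45, 90, 135),
                    contrast = c(0.4, 0.7, 0.8, 1))
  out <- filter_high_contrast(ev)
  expect_equal(out$contrast, c(0.8, 1))
})

test_that("orientation fit recovers noiseless generating parameters", {
  # widths up to ~30 degrees; with 4 distinct orientation samples, far
  # wider curves are no longer identifiable from 8 directions
  for (pars in list(c(0, 1, 45, 20), c(0.1, 0.8, 133, 28),
                    c(-0.05, 1.5, 12, 18))) {
    resp <- tuning_curve_orientation(dirs8, pars[1], pars[2], pars[3],
                                     pars[4])
    f <- fit_orientation(resp)
    expect_true(f$fit_ok)
    expect_equal(f$C, pars[1], tolerance = 1e-4)
    expect_equal(f$Rp, pars[2], tolerance = 1e-4)
    expect_equal(f$theta_pref, pars[3] %% 180, tolerance = 1e-3)
    expect_equal(f$sigma, pars[4], tolerance = 1e-3)
    # optimizer never worsens the best grid start
    sse_grid <- min(vapply(dirs8, function(th)
      sum((tuning_curve_orientation(dirs8, min(resp),
                                    max(resp) - min(resp), th, 25) -
             resp)^2), numeric(1)))
    expect_lte(f$sse, sse_grid + 1e-12)
  }
})

test_that("direction fit recovers noiseless parameters and symmetries", {
  resp <- tuning_curve_direction(dirs8, 0.02, 1.2, 0.4, 200, 30)
  f <- fit_direction(resp)
  expect_true(f$fit_ok)
  expect_equal(f$Rp, 1.2, tolerance = 1e-3)
  expect_equal(f$Rn, 0.4, tolerance = 1e-3)
  expect_equal(f$theta_pref, 200, tolerance = 1e-2)
  expect_equal(f$sigma, 30, tolerance = 1e-2)
  # Rn = 0 reduces to a single peak
  resp1 <- tuning_curve_direction(dirs8, 0, 1, 0, 90, 25)
  f1 <- fit_direction(resp1)
  expect_lt(abs(f1$Rn), 1e-3)
  expect_equal(f1$Rp, 1, tolerance = 1e-3)
  # symmetric bidirectional data gives Rp ~ Rn
  resp2 <- tuning_curve_direction(dirs8, 0, 0.9, 0.9, 135, 28)
  f2 <- fit_direction(resp2)
  expect_equal(f2$Rp, f2$Rn, tolerance = 1e-3)
})

test_that("flat responses give a degenerate but flagged orientation fit", {
  f <- fit_orientation(rep(0.5, 8))
  expect_lt(abs(f$Rp), 1e-4)
})

test_that("noisy battery recovers preferred orientation at SNR 5", {
  # single-trial SNR = Rp / noise SD = 5, averaged over 10 trials per
  # direction before fitting
  set.seed(11)
  errs <- replicate(60, {
    th <- runif(1, 0, 180)
    trials <- replicate(10, tuning_curve_orientation(dirs8, 0.05, 1, th,
                                                     25) +
                          rnorm(8, sd = 0.2))
    f <- fit_orientation(rowMeans(trials))
    d <- abs(f$theta_pref - th) %% 180
    min(d, 180 - d)
  })
  expect_lt(median(errs), 5)
})

test_that("1-CircVar matches the complex-sum formula and its limits", {
  # equal responses cancel; a single active direction saturates
  expect_equal(circ_var_selectivity(rep(1, 8), dirs8, "orientation"), 0,
               tolerance = 1e-12)
  one <- c(1, rep(0, 7))
  expect_equal(circ_var_selectivity(one, dirs8, "orientation"), 1)
  expect_equal(circ_var_selectivity(one, dirs8, "direction"), 1)
  # direct formula oracle on the worked vector
  r <- c(1, .5, .2, .1, .1, .1, .2, .5)
  rn <- r / max(r)
  th <- dirs8 * pi / 180
  oracle_ori <- Mod(sum(rn * exp(2i * th))) / sum(abs(rn))
  oracle_dir <- Mod(sum(rn * exp(1i * th))) / sum(abs(rn))
  expect_equal(circ_var_selectivity(r, dirs8, "orientation"), oracle_ori)
  expect_equal(circ_var_selectivity(r, dirs8, "direction"), oracle_dir)
  # invariance to positive rescaling; NA for all-zero input
  expect_equal(circ_var_selectivity(3.2 * r, dirs8, "orientation"),
               oracle_ori)
  expect_warning(v <- circ_var_selectivity(rep(0, 8), dirs8), "undefined")
  expect_true(is.na(v))
})

test_that("tuning-curve alignment matches index arithmetic", {
  # identical neurons with different preferred directions align identically
  base <- tuning_curve_direction(dirs8, 0, 1, 0.3, 0, 30)
  curves <- rbind(base,
                  tuning_curve_direction(dirs8, 0, 1, 0.3, 90, 30),
                  tuning_curve_direction(dirs8, 0, 1, 0.3, 225, 30))
  al <- align_tuning_curves(curves, c(0, 90, 225))
  expect_equal(al$aligned[1, ], al$aligned[2, ], tolerance = 1e-12)
  expect_equal(al$aligned[1, ], al$aligned[3, ], tolerance = 1e-12)
  # peak sits at the centre bin (relative direction 0)
  expect_equal(al$rel_directions[which.max(al$mean)], 0)
  # single neuron: alignment is a pure circular shift
  al1 <- align_tuning_curves(curves[2, , drop = FALSE], 90)
  expect_equal(sort(al1$aligned[1, ]), sort(curves[2, ]))
  # random battery against an index-arithmetic oracle
  set.seed(12)
  rc <- matrix(rnorm(16), 2, 8)
  th <- c(47, 310)
  alr <- align_tuning_curves(rc, th)
  for (i in 1:2) {
    pref_bin <- which.min(pmin(abs(dirs8 - th[i]), abs(dirs8 - th[i] - 360),
                               abs(dirs8 - th[i] + 360)))
    shift <- (pref_bin - 5) %% 8
    expect_equal(alr$aligned[i, ], rc[i, ((seq_len(8) - 1 + shift) %% 8) + 1])
  }
})
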