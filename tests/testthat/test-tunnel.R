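# Virtual-tunnel analyses: binning, clustering, BD separability,
# mismatch correction, onsets.

tunnel_fixture <- function(seed = 61, ...) {
  gt <- make_ground_truth(n_chc = 4, n_pyc = 20, seed = seed)
  out <- make_tunnel_session(gt, n_trials = 20, seed = seed + 1, ...)
  out$gt <- gt
  out$dff <- out$session$F / 100 - 1
  out
}

test_that("trial filtering enforces duration and mismatch rules", {
  fx <- tunnel_fixture(mismatch_fraction = 0.25)
  flt <- filter_tunnel_trials(fx$session, fx$events)
  mm_trials <- unique(fx$session$trial[
    fx$events$frame[fx$events$type == "mismatch"] + 1])
  expect_true(all(!(mm_trials %in% flt$kept)))
  expect_setequal(flt$excluded_mismatch, mm_trials)
  # keeping mismatch trials only drops slow ones
  flt2 <- filter_tunnel_trials(fx$session, fx$events,
                               drop_mismatch = FALSE)
  expect_setequal(flt2$kept, setdiff(1:20, flt2$excluded_slow))
  # an absurdly strict duration limit excludes everything
  flt3 <- filter_tunnel_trials(fx$session, fx$events,
                               max_duration_s = 0.1)
  expect_equal(length(flt3$kept), 0)
})

test_that("position binning reproduces constructed profiles", {
  fx <- tunnel_fixture(mismatch_fraction = 0)
  s <- fx$session
  # constant activity gives a constant profile
  const <- matrix(2.5, 1, length(s$speed))
  prof <- bin_by_position(const, s)
  expect_equal(as.numeric(prof), rep(2.5, 50))
  # activity equal to position gives a profile at the bin means
  posact <- matrix(ifelse(is.na(s$position), 0, s$position), 1)
  prof2 <- bin_by_position(posact, s)
  centers <- attr(prof2, "bin_centers")
  expect_lt(max(abs(prof2 - centers)), 1)  # within a bin width
  expect_equal(length(attr(prof2, "empty_bins")), 0)
})

test_that("tunnel visual response is the stimulus-minus-start contrast", {
  prof <- matrix(1, 1, 50)
  expect_equal(tunnel_visual_response(prof), 0)
  # step of height h at 20 cm
  step <- matrix(0, 1, 50); step[1, 11:50] <- 1.7
  expect_equal(unname(tunnel_visual_response(step)[1]), 1.7)
  # random profile against an index-window oracle
  set.seed(62)
  rp <- matrix(rnorm(50), 1, 50)
  centers <- (1:50 - 0.5) * 2
  oracle <- mean(rp[centers > 20 & centers < 80]) -
    mean(rp[centers < 20])
  expect_equal(unname(tunnel_visual_response(rp)[1]), oracle)
})

test_that("clustering finds constructed blob structure", {
  set.seed(63)
  # raw blobs separated by a mean offset (shape z-scoring disabled)
  two <- rbind(matrix(rnorm(15 * 10, 0, 0.3), 15, 10),
               matrix(rnorm(15 * 10, 4, 0.3), 15, 10))
  cl2 <- cluster_pycs(two, zscore = FALSE)
  expect_equal(cl2$k, 2)
  expect_equal(length(unique(cl2$labels[1:15])), 1)
  expect_equal(length(unique(cl2$labels[16:30])), 1)
  three <- rbind(two,
                 matrix(c(rnorm(10 * 5, -6, 0.3),
                          rnorm(10 * 5, 6, 0.3)), 10, 10))
  cl3 <- cluster_pycs(three, zscore = FALSE)
  expect_equal(cl3$k, 3)
  # shape-based (z-scored) clustering separates opposite profile shapes
  shape <- rbind(matrix(rep(sin(1:10), 12), 12, 10, byrow = TRUE),
                 matrix(rep(-sin(1:10), 12), 12, 10, byrow = TRUE)) +
    matrix(rnorm(240, sd = 0.2), 24, 10)
  cls <- cluster_pycs(shape)
  expect_equal(cls$k, 2)
  expect_equal(length(unique(cls$labels[1:12])), 1)
  expect_error(suppressWarnings(cluster_pycs(matrix(1, 10, 5))),
               "identical")
})

test_that("tunnel generator separates V and NV pyramidal clusters", {
  fx <- tunnel_fixture(mismatch_fraction = 0, noise_sd = 0.05)
  flt <- filter_tunnel_trials(fx$session, fx$events)
  pyc <- which(fx$session$cell_type == "PyC")
  prof <- bin_by_position(fx$dff[pyc, ], fx$session, trials = flt$kept)
  cl <- cluster_pycs(prof)
  expect_equal(cl$k, 2)
  agree <- table(cl$labels, fx$gt$cluster_id[pyc])
  expect_equal(min(apply(agree, 1, max)) + max(apply(agree, 1, min)),
               max(apply(agree, 1, max)))  # permutation-perfect labels
})

test_that("Bhattacharyya distance: identity, toy value, symmetry, Inf", {
  # identical samples on shared bins give BD = 0
  x <- rnorm(40)
  br <- seq(min(x), max(x), length.out = 6)
  expect_equal(chctools:::bd_statistic(x, x, br), 0)
  # two-bin toy: P = (.5, .5), Q = (.25, .75)
  expect_equal(chctools:::bd_statistic(c(1, 1, 2, 2), c(1, 2, 2, 2),
                                       breaks = c(0.5, 1.5, 2.5)),
               -log(sqrt(0.125) + sqrt(0.375)))
  # symmetric in the two samples (random histograms)
  set.seed(64)
  for (k in 1:5) {
    a <- rnorm(30); b <- rnorm(25, 0.5)
    brk <- seq(min(c(a, b)), max(c(a, b)), length.out = 8)
    expect_equal(chctools:::bd_statistic(a, b, brk),
                 chctools:::bd_statistic(b, a, brk))
    expect_gte(chctools:::bd_statistic(a, b, brk), 0)
  }
  # disjoint supports: BD infinite, handled as maximally separable
  sep <- bd_separability(c(rep(0, 10), rep(100, 10)),
                         rep(1:2, each = 10), n_bins = 4, n_perm = 200,
                         seed = 1)
  expect_true(is.infinite(sep$bd))
  expect_lt(sep$p, 0.05)
})

test_that("BD permutation test is significant only for real structure", {
  sc <- c(rnorm(25, -2, 0.5), rnorm(25, 2, 0.5))
  lab <- rep(1:2, each = 25)
  sep <- bd_separability(sc, lab, n_perm = 500, seed = 2)
  expect_lt(sep$p, 0.05)
  expect_gt(sep$bd, 0)
  # shuffled labels lose significance most of the time
  set.seed(65)
  ps <- vapply(1:10, function(k)
    bd_separability(rnorm(50), lab, n_perm = 200, seed = k)$p,
    numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
  expect_error(bd_separability(sc, rep(1, 50)), "two clusters")
})

test_that("mismatch correction recovers an injected transient", {
  fx <- tunnel_fixture(seed = 66, mismatch_fraction = 0.3,
                       mismatch_amp = 0, noise_sd = 0.02)
  s <- fx$session
  fr <- s$frame_rate
  # inject a known additive transient on one neuron at mismatch onsets
  mm_frames <- fx$events$frame[fx$events$type == "mismatch"]
  dff <- fx$dff
  a <- 0.8
  len <- chctools:::s_to_frames(1.2, fr)
  for (f in mm_frames) {
    idx <- (f + 1 + round(0.1 * fr)):(f + len)
    dff[1, idx] <- dff[1, idx] + a
  }
  mm <- mismatch_response(dff, s, fx$events, n_resample = 50, seed = 3)
  expect_equal(unname(mm$amplitude[1]), a, tolerance = 0.1)
  # neurons without a transient stay near zero
  expect_lt(max(abs(mm$amplitude[-1])), 0.15)
})

test_that("mismatch events without matched controls are dropped", {
  fx <- tunnel_fixture(seed = 67, mismatch_fraction = 1)
  # with every trial a mismatch trial there are no control trials:
  # every event is dropped with a warning and the call errors out
  expect_error(suppressWarnings(
    mismatch_response(fx$dff, fx$session, fx$events, n_resample = 10,
                      seed = 1)),
    "usable")
})

test_that("locomotion onsets match the two-window speed rule", {
  fr <- 10
  # brute-force enumeration of the rule: mean speed < thresh in the 0.5 s
  # before a frame and > thresh in the 2 s after; first frame per bout
  enumerate <- function(speed, thresh = 5) {
    hits <- integer(0)
    for (t in 6:(length(speed) - 20)) {
      if (mean(speed[(t - 5):(t - 1)]) < thresh &&
          mean(speed[t:(t + 19)]) > thresh) hits <- c(hits, t)
    }
    if (length(hits) == 0) return(integer(0))
    hits[c(TRUE, diff(hits) > 20)] - 1L
  }
  # step from rest to running gives a single onset where the forward
  # average first crosses the threshold
  speed <- c(rep(0, 50), rep(10, 50))
  on <- detect_locomotion_onsets(speed, fr)
  expect_equal(on, enumerate(speed))
  expect_equal(length(on), 1)
  expect_equal(length(detect_locomotion_onsets(rep(0, 100), fr)), 0)
  expect_equal(length(detect_locomotion_onsets(rep(10, 100), fr)), 0)
  # synthetic bout train: two bouts, counts match the enumeration
  sp <- c(rep(0, 30), rep(10, 40), rep(0, 40), rep(10, 40), rep(0, 10))
  on2 <- detect_locomotion_onsets(sp, fr)
  expect_equal(on2, enumerate(sp))
  expect_equal(length(on2), 2)
  # restriction masks out the first bout
  mask <- rep(FALSE, length(sp)); mask[100:160] <- TRUE
  on3 <- detect_locomotion_onsets(sp, fr, restrict = mask)
  expect_equal(on3, on2[on2 >= 99])
  expect_equal(length(on3), 1)
})

test_that("flow-onset responses and the speed filter behave as stated", {
  fr <- 10
  traces <- matrix(0, 1, 300)
  # boxcar covering the 0.5-2 s response window after an onset at frame
  # 100 (0-based): samples at t in [0.5, 2] are trace columns 106-121
  traces[1, 106:121] <- 2
  out <- flow_onset_response(traces, 100, fr)
  expect_equal(unname(out$amplitude[1]), 2)
  expect_equal(unname(flow_onset_response(matrix(0, 1, 300), 100,
                                          fr)$amplitude[1]), 0)
  # events at 4 or 31 cm/s are excluded by the 5-30 cm/s filter
  speed <- rep(0, 300)
  speed[101] <- 4; speed[151] <- 20; speed[201] <- 31
  out2 <- flow_onset_response(traces, c(100, 150, 200), fr,
                              speed = speed, speed_range = c(5, 30))
  expect_equal(out2$kept_events, 150)
})

test_that("ChC-cluster correlations identify the matching profile", {
  set.seed(68)
  nvm <- rnorm(200); vm <- rnorm(200)
  pyc <- rbind(nvm + rnorm(200, sd = 0.3), nvm + rnorm(200, sd = 0.3),
               vm + rnorm(200, sd = 0.3), vm + rnorm(200, sd = 0.3))
  chc <- rbind(nvm)
  out <- chc_cluster_correlation(chc, pyc, c("NV", "NV", "V", "V"))
  expect_gt(out$r_cluster_NV[1], out$r_cluster_V[1])
  # single-pair toy equals direct Pearson
  out2 <- chc_cluster_correlation(rbind(vm), rbind(pyc[3, ]), "V")
  expect_equal(out2$r_cluster_V[1], cor(vm, pyc[3, ]))
  # orthogonal profiles correlate near zero
  expect_lt(abs(out$r_cluster_V[1]), 0.2)
})
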