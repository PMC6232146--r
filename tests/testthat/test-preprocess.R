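test_that("band-pass keeps a passband tone, kills DC, adds no delay", {
  fs <- 1000
  tt <- seq(1 / fs, 20, by = 1 / fs)
  x <- sin(2 * pi * 10 * tt)
  y <- bandpass_filter(x, 0.1, 40, fs)
  mid <- 5000:15000
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.05)
  # zero-phase: cross-correlation of input and output peaks at lag zero
  cc <- ccf(x[mid], y[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # constant signal is outside the 0.1-Hz high-pass edge (judged away from
  # the edges; the 0.1-Hz transient decays over tens of seconds)
  yc <- bandpass_filter(rep(1, 60000), 0.1, 40, fs)
  expect_lt(max(abs(yc[25000:35000])), 0.05)
  expect_error(bandpass_filter(x, 0.1, 600, fs), "fs/2")
  expect_error(bandpass_filter(x[1:20], 0.1, 40, fs), "too short")
})

test_that("filter plus downsampling preserves the band, rejects 50 Hz", {
  fs <- 1000
  tt <- seq(1 / fs, 15, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * tt)
  d <- downsample(bandpass_filter(x10, 0.1, 40, fs), fs, 100)
  expect_length(d, 1500)
  sp <- Mod(fft(d[301:1300]))[1:500]
  expect_equal(which.max(sp) - 1, 100)   # 10 Hz in a 10-s window
  x50 <- sin(2 * pi * 50 * tt)
  d50 <- downsample(bandpass_filter(x50, 0.1, 40, fs), fs, 100)
  atten <- 20 * log10(max(abs(d50[301:1300])))
  expect_lt(atten, -20)
})

test_that("downsampling keeps constants and errors on non-integer ratios", {
  expect_equal(downsample(rep(2, 1000), 1000, 100), rep(2, 100),
               tolerance = 1e-6)
  expect_equal(ncol(downsample(matrix(rnorm(3000), 2), 300, 100)), 500)
  expect_error(downsample(rnorm(100), 250, 100), "integer multiple")
})

test_that("epoching yields one 1500-sample epoch per trial in condition order", {
  p <- generate_protocol(6, 2, seed = 3)
  lay <- tiny_layout()
  eff <- effect_spec(5, 5, model = NULL, effect_size = 0)
  rec <- synthesize_session(p, lay, eff, seed = 21)
  ep <- epoch_trials(rec)
  expect_length(ep$epochs, 12)
  expect_equal(dim(ep$epochs[[1]]$eeg), c(61, 1500))
  expect_equal(dim(ep$epochs[[1]]$emg), c(8, 3000))
  expect_equal(dim(ep$epochs[[1]]$joints), c(19, 1500))
  expect_equal(dim(ep$epochs[[1]]$accel), c(3, 750))
  conds <- vapply(ep$epochs, `[[`, numeric(1), "condition")
  expect_equal(conds, rep(1:6, each = 2))   # reordered from block order

  # a truncated recording flags the cut trial as incomplete
  cut <- rec
  cut$eeg <- cut$eeg[, 1:(11 * 1500)]
  ep2 <- epoch_trials(cut)
  rej <- vapply(ep2$epochs, `[[`, logical(1), "rejected")
  expect_equal(sum(rej), 1)
  expect_equal(ep2$epochs[[which(rej)]]$reason, "incomplete")
})

test_that("change-point detection matches its definition on canonical signals", {
  y <- c(rep(0, 50), rep(1, 50))
  expect_equal(detect_changepoint(y), 50)
  expect_true(is.na(detect_changepoint(rep(3, 100))))
  expect_error(detect_changepoint(rnorm(8), min_seg = 5), "shorter")
})

test_that("change-point equals the exhaustive-split oracle on piecewise signals", {
  cases <- list()
  for (n in c(30, 81, 200)) {
    for (tau in c(7, n %/% 3, n %/% 2, n - 9)) {
      cases[[length(cases) + 1]] <-
        c(rep(0, tau), rep(1.5, n - tau))                       # mean step
      cases[[length(cases) + 1]] <-
        c(seq(0, 1, length.out = tau),
          1 + 3 * seq_len(n - tau) / n)                         # slope break
      cases[[length(cases) + 1]] <-
        c(0.5 * seq_len(tau), 0.5 * tau - 2 * seq_len(n - tau)) # ramp down
    }
  }
  for (y in cases) {
    expect_identical(detect_changepoint(y), oracle_changepoint(y))
  }
  # and on pure lines / constants both report no change
  for (y in list(rep(1, 60), seq(0, 5, length.out = 60))) {
    expect_identical(detect_changepoint(y), oracle_changepoint(y))
  }
})

test_that("onsets are recovered exactly from noiseless accelerometer data", {
  p <- generate_protocol(8, 1, seed = 2)
  acc <- synthesize_accelerometer(p, onset_jitter_sd = 0.06, noise_sd = 0,
                                  seed = 4)
  for (tr in seq_len(8)) {
    epoch <- acc$signal[, (tr - 1) * 750 + 1:750, drop = FALSE]
    got <- detect_movement_onset(epoch)
    expect_equal(got$onset_sample, acc$truth$onset_sample[tr])
  }
  # a zero-amplitude step yields no onset
  flat <- synthesize_accelerometer(p, amplitude = 0, noise_sd = 0, seed = 4)
  expect_true(is.na(detect_movement_onset(flat$signal[, 1:750])$onset_sample))
})

test_that("trial rejection removes exactly the injected artifact trials", {
  p <- generate_protocol(6, 2, seed = 9)
  lay <- tiny_layout()
  eff <- effect_spec(3, 3, model = NULL, effect_size = 0)
  rec <- synthesize_session(p, lay, eff, seed = 31)
  bad <- data.frame(trial = c(2, 5, 9),
                    kind = c("movement_during_observation",
                             "tracking_glitch",
                             "movement_during_observation"))
  rec2 <- inject_artifact_trials(rec, bad, seed = 1)
  ep <- grasprsa:::detect_onsets(epoch_trials(rec2))
  rj <- reject_trials(ep)
  expect_equal(sum(rj$report$rejected), 3)
  rep_bad <- rj$report[rj$report$rejected, ]
  expect_setequal(rep_bad$trial, bad$trial)
  expect_equal(rep_bad$reason[match(bad$trial, rep_bad$trial)],
               c("movement", "tracking", "movement"))
  expect_length(rj$epochs$epochs, 9)

  # clean session: zero rejections
  ep0 <- grasprsa:::detect_onsets(epoch_trials(rec))
  expect_equal(sum(reject_trials(ep0)$report$rejected), 0)
})

test_that("all trials of a condition rejected flags it unusable", {
  p <- generate_protocol(5, 1, seed = 9)
  lay <- tiny_layout()
  rec <- synthesize_session(p, lay, effect_spec(3, 3), seed = 13)
  tr <- p$trials$trial[p$trials$condition == 2]
  rec2 <- inject_artifact_trials(
    rec, data.frame(trial = tr, kind = "tracking_glitch"))
  ep <- grasprsa:::detect_onsets(epoch_trials(rec2))
  expect_warning(rj <- reject_trials(ep), "unusable")
  expect_equal(rj$unusable_conditions, 2L)
})

test_that("the EMG envelope recovers tones and modulators", {
  fs <- 200
  tt <- seq(1 / fs, 5, by = 1 / fs)
  tone <- sin(2 * pi * 8 * tt)
  env <- emg_envelope(tone)
  expect_equal(mean(env[200:800]), sqrt(2), tolerance = 1e-3)
  expect_true(all(env >= 0))
  mod <- 1 + 0.8 * sin(2 * pi * 0.7 * tt)
  am <- mod * sin(2 * pi * 30 * tt)
  env2 <- emg_envelope(am)
  expect_gt(cor(env2[100:900], mod[100:900]), 0.99)
  expect_error(emg_envelope(rbind(tone, 0 * tt)), "constant")
})

test_that("kinematic interpolation is exact on polynomials and wrap aware", {
  set.seed(41)
  ts <- sort(runif(60, 0, 2))
  lin <- rbind(0.3 + 0.5 * ts, 1 - 0.2 * ts)
  out <- interpolate_kinematics(ts, lin, target_hz = 100, t_range = c(0.2, 1.8))
  grid <- attr(out, "time")
  expect_equal(diff(grid), rep(0.01, length(grid) - 1))
  expect_equal(out[1, ], 0.3 + 0.5 * grid, tolerance = 1e-6)
  const <- matrix(0.7, 1, 60)
  expect_equal(unique(round(interpolate_kinematics(ts, const)[1, ], 10)), 0.7)
  # a trace running through +pi keeps interpolating smoothly
  ts2 <- seq(0, 1, length.out = 50)
  wrapped <- matrix(atan2(sin(3 + 3.5 * ts2), cos(3 + 3.5 * ts2)), 1)
  w <- interpolate_kinematics(ts2, wrapped, target_hz = 200)
  expect_true(all(abs(diff(pmin(abs(diff(w[1, ])), 2 * pi - abs(diff(w[1, ]))))) < 0.1))
  expect_error(interpolate_kinematics(c(0, 1, 1, 2), matrix(1:4, 1)),
               "duplicate")
  expect_error(interpolate_kinematics(c(0, 1, 2), matrix(1:3, 1)),
               "at least 4")
})

test_that("circular mean handles wraparound and degeneracy", {
  expect_equal(circular_mean(c(0, pi / 2)), pi / 4)
  expect_equal(circular_mean(c(179, -179) * pi / 180), pi, tolerance = 1e-9)
  expect_error(circular_mean(c(0, pi)), "undefined")
  expect_error(circular_mean(numeric(0)), "empty")
})

test_that("kinematic PCA recovers low-rank structure", {
  set.seed(8)
  basis <- qr.Q(qr(matrix(rnorm(19 * 5), 19, 5)))
  scores <- matrix(rnorm(5 * 400), 5, 400)
  clean <- basis %*% scores
  p <- kinematic_pca(clean)
  expect_equal(sum(p$var_explained[1:5]), 1, tolerance = 1e-10)
  expect_warning(r1 <- kinematic_pca(outer(rnorm(19), rnorm(200))),
                 "nonzero")
  expect_equal(r1$var_explained[1], 1, tolerance = 1e-10)
  noisy <- clean + 0.05 * sd(clean) * rnorm(length(clean))
  expect_gte(sum(kinematic_pca(noisy)$var_explained[1:5]), 0.95)
  expect_error(kinematic_pca(matrix(rnorm(19 * 10), 19, 10)), "more time")
})

test_that("condition averaging is a two-level mean with exclusion logging", {
  v <- rnorm(6)
  one <- list(list(matrix(v, 1)))
  expect_equal(average_condition_patterns(one)[[1]], v)
  two <- list(list(matrix(v, 1)), list(matrix(-v, 1)))
  expect_equal(average_condition_patterns(two)[[1]], rep(0, 6))
  # permuting subjects leaves the group pattern unchanged
  subj <- lapply(1:3, function(s) lapply(1:2, function(cond)
    matrix(rnorm(8), 2, 4)))
  a <- average_condition_patterns(subj)
  b <- average_condition_patterns(subj[c(3, 1, 2)])
  expect_equal(a, b, ignore_attr = TRUE)
  # a subject lacking a condition is excluded from it and logged
  subj[[2]][[2]] <- NULL
  c <- average_condition_patterns(subj)
  excl <- attr(c, "exclusions")
  expect_equal(excl$condition, 2)
  expect_equal(excl$subject, 2)
  expect_equal(c[[2]],
               (colMeans(subj[[1]][[2]]) + colMeans(subj[[3]][[2]])) / 2)
  # circular averaging respects wraparound
  ang <- list(list(matrix(c(179, -179) * pi / 180, 2, 1)))
  expect_equal(average_condition_patterns(ang, circular = TRUE)[[1]],
               pi, tolerance = 1e-9)
})
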