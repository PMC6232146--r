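test_that("identical seeds reproduce a session bitwise", {
  p <- generate_protocol(4, 1, seed = 5)
  lay <- tiny_layout()
  eff <- effect_spec(2, 4, effect_size = 0)
  a <- synthesize_session(p, lay, eff, seed = 77)
  b <- synthesize_session(p, lay, eff, seed = 77)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$emg, b$emg)
  expect_identical(a$joints$angles, b$joints$angles)
  expect_identical(a$accel, b$accel)
  c <- synthesize_session(p, lay, eff, seed = 78)
  expect_false(identical(a$eeg, c$eeg))
})

test_that("EEG generation validates its target neighborhoods", {
  p <- generate_protocol(3, 1, seed = 1)
  lay <- tiny_layout()
  expect_error(synthesize_eeg(p, effect_spec(40, 4), lay),
               "channel neighborhood")
  expect_error(synthesize_eeg(p, effect_spec(4, 30), lay),
               "frequency neighborhood")
  expect_error(effect_spec(1, 1, effect_size = -1), "effect_size")
})

test_that("fixation and execution band power agree in a non-target cell", {
  p <- generate_protocol(4, 2, seed = 6)
  lay <- tiny_layout()
  eff <- effect_spec(10, 10, model = NULL, effect_size = 1, noise_sd = 0.3)
  eeg <- synthesize_eeg(p, eff, lay, seed = 9)
  # channel far from any suppression, frequency far from the 15-Hz target:
  # only the condition-independent oscillators and noise live there
  ch <- setdiff(lay$channels, attr(eeg, "target_channels"))[1]
  f_probe <- 33
  pows <- lapply(seq_len(nrow(p$trials)), function(tr) {
    seg <- eeg[ch, (tr - 1) * 1500 + 1:1500, drop = FALSE]
    pw <- morlet_tfr(seg, 100, freqs = f_probe, n_cycles = 7,
                     keep = c(101:300, 701:1100))
    c(fix = mean(pw[1, 1, 1:200]), ex = mean(pw[1, 1, 201:600]))
  })
  m <- do.call(rbind, pows)
  se <- sd(m[, "fix"] - m[, "ex"]) / sqrt(nrow(m))
  expect_lt(abs(mean(m[, "fix"]) - mean(m[, "ex"])), 3 * se + 1e-12)
})

test_that("EMG envelopes are condition structured and phase locked to execution", {
  p <- generate_protocol(8, 1, seed = 3)
  # conditions 1 and 2 share an activation vector, the rest sit at
  # well-separated corners of synergy space
  act <- 2 * rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(1, 1, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 1))
  set.seed(30)
  W <- matrix(abs(rnorm(24)), 8, 3)
  emg <- synthesize_emg(p, W, act, noise_sd = 0.02, seed = 12)
  env <- emg_envelope(emg)
  ph <- grasprsa:::phase_times(p)
  pats <- t(vapply(seq_len(8), function(cond) {
    tr <- p$trials$trial[p$trials$condition == cond]
    idx <- (tr - 1) * 3000 + round((ph[3] + 0.3) * 200) + 1:700
    as.vector(env[, idx])
  }, numeric(8 * 700)))
  rownames(pats) <- 1:8
  r <- compute_rdm(pats)
  expect_equal(unname(unclass(r)[1, 2]), 0)  # twins rank lowest
  # rest phase stays near baseline for every active condition
  for (tr in seq_len(8)) {
    rest <- env[, (tr - 1) * 3000 + 1:1300]
    move <- env[, (tr - 1) * 3000 + round((ph[3] + 0.4) * 200) + 1:600]
    expect_lt(mean(rest), mean(move))
  }
  expect_error(synthesize_emg(p, W, act[, 1:2]), "synergies")
  expect_error(synthesize_emg(p, W, -act), "non-negative")
})

test_that("orthogonal equal-norm activations flatten the raw EMG RDM", {
  p <- generate_protocol(8, 1, seed = 4)
  emg <- synthesize_emg(p, diag(8), diag(8), noise_sd = 0, seed = 2)
  env <- emg_envelope(emg)
  ph <- grasprsa:::phase_times(p)
  pats <- t(vapply(seq_len(8), function(cond) {
    tr <- p$trials$trial[p$trials$condition == cond]
    idx <- (tr - 1) * 3000 + round((ph[3] + 0.3) * 200) + 1:700
    as.vector(env[, idx])
  }, numeric(8 * 700)))
  d <- 1 - cor(t(pats))
  off <- d[lower.tri(d)]
  expect_lt(max(off) - min(off), 0.02 * mean(off))
})

test_that("synthetic kinematics live on the synergy subspace", {
  p <- generate_protocol(6, 2, seed = 8)
  kin0 <- synthesize_kinematics(p, noise_sd = 0, seed = 14)
  pca0 <- kinematic_pca(kin0$angles)
  expect_equal(sum(pca0$var_explained[1:5]), 1, tolerance = 1e-9)
  expect_error(
    synthesize_kinematics(p, synergy_basis = matrix(1, 19, 3)),
    "rank")
  # instantaneous sampling rate stays within 80-120 Hz
  rates <- 1 / diff(kin0$time)
  expect_true(all(rates >= 80 - 1e-6 & rates <= 120 + 1e-6))
  expect_true(all(kin0$angles > -pi & kin0$angles <= pi))
})

test_that("equal condition scores leave no condition structure in kinematics", {
  p <- generate_protocol(6, 2, seed = 10)
  scores <- matrix(rep(1, 6 * 5), 6, 5)
  kin <- synthesize_kinematics(p, condition_scores = scores,
                               noise_sd = 0.02, seed = 3)
  joints <- interpolate_kinematics(kin$time, kin$angles, target_hz = 100,
                                   t_range = c(0, 12 * 15 - 0.01))
  ph <- grasprsa:::phase_times(p)
  pats <- t(vapply(seq_len(6), function(cond) {
    tr <- p$trials$trial[p$trials$condition == cond]
    idx <- c(vapply(tr, function(k)
      (k - 1) * 1500 + round((ph[3] + 0.4) * 100) + 1:100, numeric(100)))
    as.vector(joints[, idx])
  }, numeric(19 * 200)))
  rownames(pats) <- 1:6
  model <- matrix(1, 6, 6) - diag(6)
  model[1:3, 1:3] <- 0; diag(model) <- 0
  r <- compute_rdm(pats)
  expect_lt(abs(1 - compare_rdms(r, structure(model, class = "matrix"))),
            0.75)
})

test_that("accelerometer truth matches its construction", {
  p <- generate_protocol(5, 2, seed = 2)
  a0 <- synthesize_accelerometer(p, onset_jitter_sd = 0, seed = 3)
  expect_true(all(a0$truth$onset_s == 0.3))
  expect_false(any(a0$truth$clipped))
  aj <- synthesize_accelerometer(p, onset_jitter_sd = 5, seed = 3)
  expect_true(all(aj$truth$onset_s >= 1 / 50 & aj$truth$onset_s <= 1 - 1 / 50))
  expect_true(any(aj$truth$clipped))
})

test_that("artifact injection round-trips and guards its inputs", {
  p <- generate_protocol(4, 2, seed = 2)
  lay <- tiny_layout()
  rec <- synthesize_session(p, lay, effect_spec(1, 1, effect_size = 0),
                            seed = 55)
  same <- inject_artifact_trials(rec, data.frame(trial = numeric(0),
                                                 kind = character(0)))
  expect_identical(same$accel, rec$accel)
  expect_identical(same$joints, rec$joints)
  expect_warning(
    inject_artifact_trials(rec,
                           data.frame(trial = c(3, 3),
                                      kind = rep("tracking_glitch", 2))),
    "once")
  expect_error(
    inject_artifact_trials(rec, data.frame(trial = 99,
                                           kind = "tracking_glitch")),
    "unknown trial")
  expect_error(
    inject_artifact_trials(rec, data.frame(trial = 1, kind = "nope")),
    "unknown artifact kind")
})
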