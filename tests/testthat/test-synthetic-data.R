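# Synthetic study fixtures: task kinematics, marker synthesis, EMG-like
# signals, and the loop-closing round trips.

test_that("minimum-jerk profiles meet their boundary conditions", {
  d <- 4; pk <- 1.9
  for (tt in c(0, d / 2, d)) {
    expect_equal(min_jerk_profile(tt, d, pk, deriv = 1), 0, tolerance = 1e-12)
  }
  expect_equal(min_jerk_profile(0, d, pk), 0)
  expect_equal(min_jerk_profile(d / 2, d, pk), pk, tolerance = 1e-12)
  expect_equal(min_jerk_profile(d, d, pk), 0, tolerance = 1e-12)
  # velocity is the derivative of position (finite-difference check)
  h <- 1e-6
  for (tt in c(0.7, 1.9, 3.1)) {
    fd <- (min_jerk_profile(tt + h, d, pk) - min_jerk_profile(tt - h, d, pk)) / (2 * h)
    expect_equal(min_jerk_profile(tt, d, pk, deriv = 1), fd, tolerance = 1e-6)
  }
})

test_that("task kinematics respect the task definitions", {
  m <- builtin_thoracoscapular_model()
  q0 <- default_q(m)

  shrug <- generate_task_kinematics(task_spec("shrug"), m)
  hum_cols <- c("gh_plane", "gh_elev", "gh_rot", "elbow_flexion")
  for (cc in hum_cols)
    expect_true(all(shrug[[cc]] == q0[[cc]])) # humerus stays at defaults
  expect_gt(max(shrug$scap_elevation), 0)

  flex <- generate_task_kinematics(task_spec("flexion", peak = 110 * pi / 180), m)
  # peak humerothoracic elevation (glenohumeral + scapular upward rotation)
  total <- flex$gh_elev + flex$scap_upward_rot
  expect_equal(max(total), 110 * pi / 180, tolerance = 1e-9)
  # scapulohumeral rhythm 1:2 between scapular and glenohumeral parts
  expect_equal(max(flex$scap_upward_rot) / max(flex$gh_elev), 0.5,
               tolerance = 1e-9)
  expect_true(all(flex$gh_plane == 0))

  abd <- generate_task_kinematics(task_spec("abduction"), m)
  expect_true(all(abd$gh_plane == -pi / 2))
})

test_that("marker synthesis is exact without noise and reproducible with it", {
  m <- builtin_thoracoscapular_model()
  qt <- generate_task_kinematics(task_spec("shrug", duration = 0.5), m, fs = 20)
  trc0 <- generate_marker_data(m, qt, noise_sd = 0, fs = 20, seed = 9)
  # forward-kinematics oracle
  for (f in c(1, 6, 11)) {
    mp <- marker_positions(m, as.numeric(qt[f, -1]))
    expect_equal(trc0$positions[f, , ], mp, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  t1 <- generate_marker_data(m, qt, noise_sd = 0.003, fs = 20, seed = 9)
  t2 <- generate_marker_data(m, qt, noise_sd = 0.003, fs = 20, seed = 9)
  expect_identical(t1$positions, t2$positions) # bit-reproducible
  t3 <- generate_marker_data(m, qt, noise_sd = 0.003, fs = 20, seed = 10)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("marker noise has the requested standard deviation", {
  m <- builtin_thoracoscapular_model()
  qt <- generate_task_kinematics(task_spec("shrug", duration = 2), m, fs = 60)
  clean <- generate_marker_data(m, qt, noise_sd = 0, fs = 60, seed = 1)
  noisy <- generate_marker_data(m, qt, noise_sd = 0.003, fs = 60, seed = 1)
  resid <- noisy$positions - clean$positions
  expect_gt(length(resid), 1000)
  expect_lt(abs(stats::sd(resid) - 0.003), 0.1 * 0.003) # within 10%
})

test_that("the seed battery covers 18 reproducible trials", {
  b <- task_battery(seed = 42L)
  expect_length(b, 18)
  key <- vapply(b, function(s) paste(s$task, s$hand_mass, s$trial), "")
  expect_identical(anyDuplicated(key), 0L)
  seeds <- vapply(b, `[[`, numeric(1), "seed")
  expect_identical(anyDuplicated(seeds), 0L)
  b2 <- task_battery(seed = 42L)
  expect_identical(vapply(b2, `[[`, numeric(1), "seed"), seeds)
})

test_that("synthetic EMG is recovered by the envelope chain", {
  t <- seq(0, 4, by = 1 / 120)
  act <- data.frame(time = t,
                    mus = min_jerk_profile(t, 4, 0.8))
  raw <- generate_synthetic_emg(act, fs = 1000, snr = 10, seed = 4)
  env <- emg_envelope(raw$mus, 1000)
  # round trip: envelope correlates with the driving activation
  act_i <- stats::approx(t, act$mus, raw$time)$y
  expect_gt(stats::cor(env, act_i), 0.95)

  # near-zero activation produces a near-zero envelope
  act0 <- data.frame(time = t, mus = rep(0, length(t)))
  raw0 <- generate_synthetic_emg(act0, fs = 1000, snr = 10, seed = 4)
  env0 <- emg_envelope(raw0$mus, 1000)
  # the residual is the additive sensor-noise floor: rectified mean of the
  # high-passed 1/snr noise, well below the full-scale envelope
  expect_lt(stats::median(env0), 1.2 / 10)
  expect_lt(stats::median(env0), 0.2 * max(env))

  # linearity: half activation gives about half the envelope
  actA <- data.frame(time = t, mus = rep(1, length(t)))
  actB <- data.frame(time = t, mus = rep(0.5, length(t)))
  eA <- emg_envelope(generate_synthetic_emg(actA, seed = 6)$mus, 1000)
  eB <- emg_envelope(generate_synthetic_emg(actB, seed = 6)$mus, 1000)
  mid <- 500:3500
  expect_equal(mean(eB[mid]) / mean(eA[mid]), 0.5, tolerance = 0.1)

  # reproducibility
  rawX <- generate_synthetic_emg(act, fs = 1000, snr = 10, seed = 4)
  expect_identical(rawX$mus, raw$mus)
})
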