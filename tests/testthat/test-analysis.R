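# Muscle power, positive work, external work and EMG comparison.

test_that("muscle power signs follow the concentric-positive convention", {
  expect_equal(muscle_power(100, -0.1), 10)  # shortening -> positive power
  expect_equal(muscle_power(100, 0.1), -10)  # lengthening -> negative
  expect_equal(muscle_power(0, 0.5), 0)
  expect_error(muscle_power(c(1, 2), 1), "length")
})

test_that("positive work integrates the positive part of power", {
  t <- seq(0, 2, by = 0.001)
  expect_equal(positive_work(t, rep(10, length(t))), 20, tolerance = 1e-9)
  expect_equal(positive_work(t, rep(-5, length(t))), 0)
  # sine over whole periods: only the positive half-waves count
  t2 <- seq(0, 1, by = 1e-4)
  P <- sin(2 * pi * 3 * t2) # 3 periods
  oracle <- 3 * (2 / (2 * pi * 3)) # 3 half-wave integrals of amplitude 1
  expect_equal(positive_work(t2, P), oracle, tolerance = 1e-4)
  expect_warning(w <- positive_work(t2, P, interval = c(0.5, 0.5)), "interval")
  expect_equal(w, 0)
  # refinement invariance
  t3 <- seq(0, 1, by = 1e-3)
  expect_equal(positive_work(t3, sin(2 * pi * 3 * t3)), oracle,
               tolerance = 1e-3)
})

test_that("external work is the potential-energy change of the endpoints", {
  m <- toy_pendulum_model(l = 0.25, mass = 2)
  # swing from hanging to horizontal: com rises by l
  fake <- list(time = c(0, 0.5, 1), q = matrix(c(0, 0.3, pi / 2), 3, 1,
                                               dimnames = list(NULL, "theta")))
  expect_equal(external_work(m, fake), 2 * 9.81 * 0.25, tolerance = 1e-9)
  # no net elevation -> zero
  fake2 <- list(time = c(0, 1), q = matrix(c(0.4, 0.4), 2, 1))
  expect_equal(external_work(m, fake2), 0, tolerance = 1e-12)
  # path independence: same endpoints, different interior
  fake3 <- list(time = c(0, 0.5, 1), q = matrix(c(0, -1.2, pi / 2), 3, 1))
  expect_equal(external_work(m, fake3), external_work(m, fake), tolerance = 1e-12)
})

test_that("work summary conserves totals and applies the 3% exclusion rule", {
  m <- builtin_thoracoscapular_model()
  nt <- 11; nm <- length(m$muscles)
  fake <- list(
    time = seq(0, 1, length.out = nt),
    q = matrix(rep(default_q(m), each = nt), nt,
               dimnames = list(NULL, coord_names(m))),
    F_mtu = matrix(0, nt, nm, dimnames = list(NULL, names(m$muscles))),
    v_mtu = matrix(0, nt, nm, dimnames = list(NULL, names(m$muscles))))
  fake$q[, "gh_elev"] <- seq(0, 1, length.out = nt)
  # two active muscles, one big, one tiny
  fake$F_mtu[, 1] <- 100; fake$v_mtu[, 1] <- -0.1  # 10 W
  fake$F_mtu[, 5] <- 100; fake$v_mtu[, 5] <- -0.001 # 0.1 W (< 3%)
  ws <- work_summary(m, fake, task = "flexion")
  expect_equal(sum(ws$per_muscle$positive_work_J), ws$total, tolerance = 1e-12)
  expect_equal(sum(ws$group_totals), ws$total, tolerance = 1e-12)
  big <- ws$per_muscle$muscle[1]
  expect_false(ws$per_muscle$excluded[1])
  expect_true(ws$per_muscle$excluded[ws$per_muscle$positive_work_J < 0.03 * ws$total][1])
  # idle model: all zeros
  fake$F_mtu[] <- 0
  ws0 <- work_summary(m, fake, task = "flexion")
  expect_equal(ws0$total, 0)
})

test_that("elevation-phase detection runs from onset to peak", {
  m <- builtin_thoracoscapular_model()
  nt <- 101
  t <- seq(0, 4, length.out = nt)
  q <- matrix(rep(default_q(m), each = nt), nt,
              dimnames = list(NULL, coord_names(m)))
  q[, "gh_elev"] <- pmin(t, 2) / 2 * 1.2 # ramp up, hold after t = 2
  ph <- elevation_phase(list(time = t, q = q), task = "flexion")
  expect_gte(ph[1], 0); expect_lt(ph[1], 0.3) # onset at 5% excursion
  expect_equal(ph[2], 2, tolerance = 0.1)     # peak
})

test_that("activation MAE averages serratus bundles before comparing", {
  t <- seq(0, 1, by = 0.01)
  expect_equal(activation_mae(t, rep(0.3, 101), t, rep(0.3, 101)), 0)
  expect_equal(activation_mae(t, rep(0.35, 101), t, rep(0.3, 101)), 0.05,
               tolerance = 1e-12)
  bundles <- data.frame(s1 = rep(0.1, 101), s2 = rep(0.2, 101),
                        s3 = rep(0.3, 101))
  expect_equal(activation_mae(t, bundles, t, rep(0.2, 101)), 0,
               tolerance = 1e-12)
  expect_error(activation_mae(t, rep(1, 101), t + 10, rep(1, 101)),
               "overlap")
})
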