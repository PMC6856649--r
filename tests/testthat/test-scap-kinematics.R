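# Scapulothoracic joint geometry, forward kinematics and inverse kinematics.

test_that("scapula stays on the ellipsoid surface and starts at the reference pose", {
  radii <- c(0.10, 0.21, 0.12)
  T0 <- scapula_transform(radii, c(0, 0, 0, 0))
  expect_equal(T0[1:3, 4], c(0, 0, radii[3]), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:50) {
    q <- c(stats::runif(2, -0.6, 0.6), stats::runif(1, -1, 1), 0)
    expect_lt(scapula_surface_residual(radii, q), 1e-9)
  }
  # upward rotation and winging do not move the contact point
  q <- c(0.2, -0.3, 0, 0)
  p0 <- scapula_transform(radii, q)[1:3, 4]
  p1 <- scapula_transform(radii, q + c(0, 0, 0.7, 0.4))[1:3, 4]
  expect_equal(p0, p1, tolerance = 1e-12)
})

test_that("analytic contact-point Jacobian matches central differences", {
  radii <- c(0.10, 0.21, 0.12)
  h <- 1e-6
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    q <- c(stats::runif(2, -0.6, 0.6), stats::runif(2, -0.8, 0.8))
    Ja <- scapula_contact_jacobian(radii, q)
    Jn <- matrix(0, 3, 4)
    for (j in 1:4) {
      qp <- q; qp[j] <- qp[j] + h
      qm <- q; qm[j] <- qm[j] - h
      Jn[, j] <- (scapula_transform(radii, qp)[1:3, 4] -
                    scapula_transform(radii, qm)[1:3, 4]) / (2 * h)
    }
    worst <- max(worst, max(abs(Ja - Jn)))
  }
  expect_lt(worst, 1e-6)
})

test_that("forward kinematics composes the tree and respects locality", {
  m <- builtin_thoracoscapular_model()
  q0 <- default_q(m)
  fr0 <- forward_kinematics(m, q0)
  expect_equal(fr0$thorax, diag(4))

  q <- q0; q["gh_elev"] <- pi / 2
  fr <- forward_kinematics(m, q)
  expect_equal(fr$thorax, fr0$thorax)      # humeral motion leaves thorax alone
  expect_equal(fr$scapula, fr0$scapula)    # ... and the scapula
  expect_false(isTRUE(all.equal(fr$humerus, fr0$humerus)))

  # scapular coordinates move independently of humeral coordinates
  q2 <- q0; q2["scap_elevation"] <- 0.2
  frs <- forward_kinematics(m, q2)
  expect_false(isTRUE(all.equal(frs$scapula, fr0$scapula)))
  rel_hum <- scapsim:::transform_inverse(frs$scapula) %*% frs$humerus
  rel_hum0 <- scapsim:::transform_inverse(fr0$scapula) %*% fr0$humerus
  expect_equal(rel_hum, rel_hum0, tolerance = 1e-12)
})

test_that("marker world positions match a direct rigid-transform oracle", {
  m <- builtin_thoracoscapular_model()
  set.seed(13)
  r <- coord_ranges(m)
  for (k in 1:3) {
    q <- stats::runif(nrow(r), r[, 1] * 0.4, r[, 2] * 0.4)
    frames <- forward_kinematics(m, q)
    mp <- marker_positions(m, q)
    for (mk in m$markers) {
      Tb <- frames[[mk$body]]
      oracle <- drop(Tb[1:3, 1:3] %*% mk$loc) + Tb[1:3, 4]
      expect_equal(unname(mp[mk$name, ]), oracle, tolerance = 1e-12)
    }
  }
})

test_that("coordinate range violations are reported by name", {
  m <- builtin_thoracoscapular_model()
  q <- default_q(m); q["gh_elev"] <- 5
  expect_error(forward_kinematics(m, q, check_range = TRUE), "gh_elev")
})

test_that("noise-free IK recovers the generating coordinates", {
  m <- builtin_thoracoscapular_model()
  spec <- task_spec("flexion", 0, seed = 5)
  qt <- generate_task_kinematics(spec, m)
  sub <- qt[seq(1, nrow(qt), by = 30), ]
  trc <- generate_marker_data(m, sub, noise_sd = 0, fs = 4, seed = 1)
  ik <- solve_inverse_kinematics(m, trc)
  expect_lt(ik$rmse_total, 1e-6)
  expect_lt(max(abs(ik$q - as.matrix(sub[, -1]))), 1e-3)
})

test_that("occluded markers flag the frame and the solution stays continuous", {
  m <- builtin_thoracoscapular_model()
  spec <- task_spec("shrug", 0, duration = 1, seed = 5)
  qt <- generate_task_kinematics(spec, m, fs = 20)
  trc <- generate_marker_data(m, qt, noise_sd = 0.001, fs = 20, seed = 2)
  # one marker occluded mid-trial: not flagged, still solvable
  trc$positions[8, "AA", ] <- NA
  # nearly all markers occluded on another frame: flagged + interpolated
  trc$positions[12, 1:10, ] <- NA
  ik <- solve_inverse_kinematics(m, trc)
  expect_false(ik$flagged[8])
  expect_true(ik$flagged[12])
  expect_false(anyNA(ik$q[12, ]))
  # continuity through the occlusions on the well-observed coordinates;
  # the gh_plane/gh_rot pair is gimbal-degenerate with the arm hanging
  # (noise-equivalent wander there is physical, bounded by branch flips)
  obs <- setdiff(colnames(ik$q), c("gh_plane", "gh_rot"))
  expect_lt(max(abs(diff(ik$q[, obs]))), 0.1) # rad
  expect_lt(max(abs(diff(ik$q[, c("gh_plane", "gh_rot")]))), 1.0)
})

test_that("ellipsoid calibration improves and does not regress the objective", {
  m <- builtin_thoracoscapular_model()
  # calibration trial: scapular ROM sweep; a single-coordinate motion (a
  # pure shrug) leaves radii partly compensable by the coordinates and
  # makes the fit objective a flat valley instead of a well
  grid <- expand.grid(el = seq(-0.15, 0.35, length.out = 3),
                      ab = seq(-0.25, 0.45, length.out = 3))
  qmat <- matrix(0, nrow(grid), length(m$coordinates),
                 dimnames = list(NULL, names(m$coordinates)))
  qmat[, "scap_abduction"] <- grid$ab
  qmat[, "scap_elevation"] <- grid$el
  qt <- data.frame(time = seq(0, by = 0.5, length.out = nrow(qmat)), qmat)
  trc <- generate_marker_data(m, qt, noise_sd = 0, fs = 2, seed = 2)

  # already-correct ellipsoid: (near) fixed point, objective not worsened
  fit0 <- fit_thorax_ellipsoid(m, trc, maxit = 40)
  expect_lte(fit0$objective_after, fit0$objective_before)
  ji <- which(vapply(m$joints, `[[`, character(1), "name") == "scapulothoracic")
  expect_lt(max(abs(fit0$radii / m$joints[[ji]]$params$radii - 1)), 0.02)

  # perturbed radii: objective decreases
  m_bad <- m
  m_bad$joints[[ji]]$params$radii <- m$joints[[ji]]$params$radii * c(1.06, 0.95, 1.05)
  fit <- fit_thorax_ellipsoid(m_bad, trc, maxit = 150)
  expect_lt(fit$objective_after, fit$objective_before)
})
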