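# Path lengths, wrap surfaces, tendon-excursion moment arms, operating
# range and fiber/tendon tuning.

test_that("straight paths and non-intersecting wraps reduce to distances", {
  m <- toy_hinge_model(origin = c(-0.15, 0, 0), insertion = c(0.15, 0, 0))
  expect_equal(path_length(m, 0, "m1"), 0.30, tolerance = 1e-12)

  s <- wrap_surface("w", "sphere", "ground", radii = 0.05)
  sol <- wrap_over_surface(c(-0.3, 0.2, 0), c(0.3, 0.2, 0), s)
  expect_false(sol$wrapped) # segment clears the sphere
  expect_equal(sol$length, 0.6, tolerance = 1e-12)
})

test_that("sphere wrap matches the tangent-arc closed form", {
  r <- 0.05
  s <- wrap_surface("w", "sphere", "ground", radii = r)
  # near-antipodal points hugging the sphere
  for (d in c(0.06, 0.1, 0.2)) {
    sol <- wrap_over_surface(c(-d, 0, 0), c(d, 1e-9, 0), s)
    expect_true(sol$wrapped)
    oracle <- 2 * sqrt(d^2 - r^2) + r * (pi - 2 * acos(r / d))
    expect_lt(abs(sol$length - oracle), 1e-6)
  }
  # endpoint inside the surface is the undefined-path condition
  expect_error(wrap_over_surface(c(0.01, 0, 0), c(0.3, 0, 0), s), "inside")
})

test_that("cylinder wrap matches the unrolled-geodesic closed form", {
  r <- 0.05
  cyl <- wrap_surface("w", "cylinder", "ground", radii = c(r, 0.5))
  d <- 0.12; dz <- 0.07
  sol <- wrap_over_surface(c(-d, 0, 0), c(d, 1e-9, dz), cyl)
  expect_true(sol$wrapped)
  planar <- 2 * sqrt(d^2 - r^2) + r * (pi - 2 * acos(r / d))
  expect_equal(sol$length, sqrt(planar^2 + dz^2), tolerance = 1e-7)
})

test_that("ellipsoid wrap degenerates to the sphere closed form", {
  r <- 0.08
  ell <- wrap_surface("w", "ellipsoid", "ground", radii = c(r, r, r))
  p1 <- c(-0.15, 0.02, 0.01)
  p2 <- c(0.16, -0.01, -0.02)
  sol <- wrap_over_surface(p1, p2, ell, n_points = 257, tol = 1e-12,
                           max_iter = 6000)
  sph <- wrap_over_surface(p1, p2, wrap_surface("w", "sphere", "ground",
                                                radii = r))
  expect_true(sol$wrapped && sph$wrapped)
  expect_lt(abs(sol$length - sph$length), 1e-6)
})

test_that("path length never drops below the straight-line distance", {
  m <- builtin_thoracoscapular_model()
  set.seed(3)
  r <- coord_ranges(m)
  for (k in 1:5) {
    q <- stats::runif(nrow(r), r[, 1] * 0.3, r[, 2] * 0.3)
    frames <- forward_kinematics(m, q)
    for (mu in c("SerratusAnterior.Middle", "Deltoideus.Middle",
                 "Trapezius.ScapulaSuperior")) {
      d <- path_length(m, q, mu, detail = TRUE)
      straight <- sqrt(sum((d$points[nrow(d$points), ] - d$points[1, ])^2))
      expect_gte(d$length, straight - 1e-9)
    }
  }
})

test_that("tendon-excursion moment arm equals perpendicular distance on a hinge", {
  d <- 0.03
  m <- toy_hinge_model(origin = c(-0.2, d, 0), insertion = c(0.2, d, 0))
  expect_equal(abs(moment_arm(m, 0, "m1", "theta")), d, tolerance = 1e-6)
})

test_that("moment arm matches the analytic derivative on a sphere-wrap toy", {
  # sphere centered on the hinge axis: while wrapped, dL/dtheta = radius
  r0 <- 0.04
  w <- wrap_surface("w1", "sphere", "ground", radii = r0)
  m <- toy_hinge_model(origin = c(-0.2, 0.001, 0), insertion = c(0.2, 0.001, 0),
                       wrap = w)
  # the segment intersects the sphere only for small hinge angles; beyond
  # ~0.45 rad it lifts off and the arm reverts to the chord's perpendicular
  # distance, so probe inside the wrapped band on both sides
  for (th in c(-0.3, -0.15, 0.15, 0.3)) {
    expect_equal(abs(moment_arm(m, th, "m1", "theta")), r0, tolerance = 1e-5)
  }
})

test_that("a muscle not crossing a joint has zero moment arm", {
  m <- builtin_thoracoscapular_model()
  q0 <- default_q(m)
  # coracobrachialis runs scapula -> humerus: no scapulothoracic crossing
  expect_equal(moment_arm(m, q0, "Coracobrachialis", "scap_elevation"), 0)
  # and the structural dependency map says so
  deps <- muscle_coord_dependencies(m)
  expect_false("scap_elevation" %in% deps$Coracobrachialis)
  expect_true("gh_elev" %in% deps$Coracobrachialis)
})

test_that("musculotendon lengths are continuous over the task range of motion", {
  m <- builtin_thoracoscapular_model()
  q0 <- default_q(m)
  cache <- new.env(parent = emptyenv())
  step_deg <- 0.5
  # abduction-with-rhythm sweep, 0..110 deg of humeral elevation
  n <- round(110 / step_deg)
  Lprev <- NULL
  worst <- 0
  for (i in 0:n) {
    f <- i / n
    q <- q0
    q["gh_plane"] <- -pi / 2
    q["gh_elev"] <- f * 110 * pi / 180
    q["scap_upward_rot"] <- f * 55 * pi / 180
    L <- muscle_lengths(m, q, cache = cache)
    if (!is.null(Lprev)) worst <- max(worst, max(abs(L - Lprev)))
    Lprev <- L
  }
  expect_lt(worst, 0.002) # < 2 mm per 0.5 degree step
})

test_that("operating-range report equals a brute-force scan", {
  m <- builtin_thoracoscapular_model()
  spec <- task_spec("flexion", 0, seed = 9)
  qt <- generate_task_kinematics(spec, m)
  sub <- as.matrix(qt[seq(1, nrow(qt), by = 60), -1])
  rep <- check_fiber_operating_range(m, sub)
  # brute force: recompute every sample by hand
  for (i in sample(seq_len(nrow(rep)), 8)) {
    p <- m$muscles[[rep$muscle[i]]]$params
    ratios <- apply(sub, 1, function(qr) {
      L <- path_length(m, qr, rep$muscle[i])
      max(L - p$l_ts, 0) / cos(p$pennation * pi / 180) / p$l_opt
    })
    expect_equal(rep$min_ratio[i], min(ratios), tolerance = 1e-9)
    expect_equal(rep$max_ratio[i], max(ratios), tolerance = 1e-9)
    expect_identical(rep$flag_high[i], max(ratios) > 1.5)
    expect_identical(rep$flag_low[i], min(ratios) < 0.5)
  }
})

test_that("fiber/tendon tuning follows the +2% / same-length rule", {
  # unflagged model is a fixed point
  m <- toy_hinge_model(origin = c(-0.15, 0.02, 0), insertion = c(0.15, 0.02, 0),
                       l_opt = 0.2, l_ts = 0.1) # MTU 0.30 -> ratio 1.0
  tu <- tune_muscle_lengths(m, matrix(0, 1, 1))
  expect_identical(nrow(tu$log), 0L)
  expect_equal(tu$model$muscles$m1$params$l_opt, 0.2)

  # over-stretched muscle: >= 1 step applied, final ratio <= 1.5
  m2 <- toy_hinge_model(origin = c(-0.15, 0.02, 0),
                        insertion = c(0.15, 0.02, 0),
                        l_opt = 0.13, l_ts = 0.1) # ratio ~ 1.54 at theta 0
  tu2 <- tune_muscle_lengths(m2, matrix(0, 1, 1))
  expect_gte(nrow(tu2$log), 1L)
  p <- tu2$model$muscles$m1$params
  L <- path_length(tu2$model, 0, "m1")
  expect_lte((L - p$l_ts) / p$l_opt, 1.5)
  # each logged step: l_opt multiplied by 1.02, l_ts reduced by the same length
  expect_equal(tu2$log$l_opt_new, tu2$log$l_opt_old * 1.02, tolerance = 1e-12)
  expect_equal(tu2$log$l_ts_old - tu2$log$l_ts_new,
               pmin(0.02 * tu2$log$l_opt_old, tu2$log$l_ts_old),
               tolerance = 1e-12)

  # zero tendon slack needing shortening: clamped at 0 and reported
  m3 <- toy_hinge_model(l_opt = 0.18, l_ts = 0) # ratio 0.40/0.18 = 2.2, l_ts 0
  tu3 <- tune_muscle_lengths(m3, matrix(0, 1, 1))
  expect_equal(tu3$model$muscles$m1$params$l_ts, 0)
  expect_true("m1" %in% tu3$unresolved ||
                (path_length(tu3$model, 0, "m1") / tu3$model$muscles$m1$params$l_opt) <= 1.5)
})
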