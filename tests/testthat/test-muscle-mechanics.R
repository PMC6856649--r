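# Rigid-tendon Hill-type force generation and activation dynamics.

test_that("rigid-tendon fiber kinematics follow the geometric construction", {
  p0 <- muscle_parameters("zero_slack", "", 387.8, 0.0945, 0) # l_ts = 0
  fk <- fiber_kinematics(p0, l_mtu = 0.12, v_mtu = 0.05)
  expect_equal(fk$l_fiber, 0.12)
  expect_equal(fk$v_fiber, 0.05)
  expect_false(fk$slack)

  p <- muscle_parameters("m", "", 100, l_opt = 0.1, l_ts = 0.05)
  fk2 <- fiber_kinematics(p, l_mtu = 0.15) # l_ts + l_opt
  expect_equal(fk2$l_fiber, 0.1)
  expect_equal(fk2$v_fiber, 0)

  pp <- muscle_parameters("penn", "", 100, 0.1, 0.05, pennation = 30)
  fk3 <- fiber_kinematics(pp, l_mtu = 0.15, v_mtu = 0.02)
  expect_equal(fk3$l_fiber, 0.1 / cos(pi / 6))
  expect_equal(fk3$v_fiber, 0.02 / cos(pi / 6))

  slack <- fiber_kinematics(p, l_mtu = 0.04)
  expect_true(slack$slack)
  expect_equal(tendon_force(p, 0.04, 0, a = 1), 0)
})

test_that("maximal isometric force at optimum equals F_max cos(pennation) for all 33", {
  m <- builtin_thoracoscapular_model()
  for (mus in m$muscles) {
    p <- mus$params
    l_mtu <- p$l_ts + p$l_opt * cos(p$pennation * pi / 180)
    F <- tendon_force(p, l_mtu, 0, a = 1)
    expect_equal(F, p$f_max * cos(p$pennation * pi / 180), tolerance = 1e-9)
  }
})

test_that("force is monotone in activation and passive-free below optimum", {
  p <- muscle_parameters("m", "", 1043, 0.1127, 0.027)
  l <- p$l_ts + 0.9 * p$l_opt
  expect_equal(tendon_force(p, l, 0, a = 0), 0) # no passive force below l_opt
  as <- seq(0, 1, by = 0.1)
  Fs <- vapply(as, function(a) tendon_force(p, l, 0, a), numeric(1))
  expect_true(all(diff(Fs) > 0))
})

test_that("force is continuous in MTU length across the slack transition", {
  p <- muscle_parameters("m", "", 500, 0.1, 0.05)
  ls <- seq(0.045, 0.065, by = 5e-5)
  Fs <- vapply(ls, function(l) tendon_force(p, l, 0, a = 1), numeric(1))
  expect_lt(max(abs(diff(Fs))), 1.0) # no jump at l_mtu = l_ts (0.05)
  i <- which.min(abs(ls - 0.05))
  expect_lt(Fs[i + 1], 5) # force departs from ~0 at the transition
})

test_that("force-velocity curve has the Hill shape with eccentric plateau", {
  cur <- hill_curves()
  expect_equal(scapsim:::force_velocity(0, cur), 1)
  expect_equal(scapsim:::force_velocity(-1, cur), 0) # at max shortening speed
  expect_lt(scapsim:::force_velocity(-0.5, cur), 1)
  expect_gt(scapsim:::force_velocity(0.5, cur), 1)
  expect_lt(scapsim:::force_velocity(10, cur), cur$flen + 1e-9)
  # C0 continuity and monotonicity around zero
  v <- seq(-0.2, 0.2, by = 1e-3)
  fv <- scapsim:::force_velocity(v, cur)
  expect_true(all(diff(fv) > 0))
})

test_that("activation dynamics match the closed-form exponential", {
  # equilibrium
  expect_equal(activation_dynamics(0.4, 0.4, 0.01), 0.4)
  # monotone approach to a step excitation
  a <- 0
  trace <- numeric(200)
  for (i in 1:200) { a <- activation_dynamics(a, 1, 0.001); trace[i] <- a }
  expect_true(all(diff(trace) > 0))
  expect_gt(trace[200], 0.99)
  # discrete solution vs exact ODE solution for piecewise-constant u
  for (ud in list(c(1, 0.01), c(0, 0.04))) {
    u <- ud[1]; tau <- ud[2]
    a0 <- 0.5
    a <- a0
    n <- 137; dt <- 0.0007
    for (i in 1:n) a <- activation_dynamics(a, u, dt)
    exact <- u + (a0 - u) * exp(-n * dt / tau)
    expect_lt(abs(a - exact), 1e-6)
  }
  # clamped to [0, 1]
  expect_lte(activation_dynamics(0.999, 1, 1), 1)
  expect_gte(activation_dynamics(0.001, 0, 1), 0)
})
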