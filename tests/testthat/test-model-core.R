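# Built-in model integrity and the domain-type validators.

test_that("the built-in model carries exactly the 33 published actuators", {
  m <- builtin_thoracoscapular_model()
  expect_length(m$muscles, 33)
  expect_identical(nrow(builtin_muscle_table()), 33L)
  # each table row appears exactly once
  expect_setequal(names(m$muscles), builtin_muscle_table()$name)

  dm <- m$muscles[["Deltoideus.Middle"]]$params
  expect_equal(dm$f_max, 2597.8)
  expect_equal(dm$l_opt, 0.0748)
  expect_equal(dm$l_ts, 0.064)
  expect_equal(dm$pennation, 5)

  ss <- m$muscles[["SerratusAnterior.Superior"]]$params
  expect_equal(ss$f_max, 387.8)
  expect_equal(ss$l_opt, 0.0945)
  expect_identical(ss$l_ts, 0) # zero tendon slack is permitted

  tls <- m$muscles[["TricepsLong"]]$params
  expect_equal(tls$pennation, 10)
})

test_that("parameter validation rejects non-physical architectures", {
  expect_error(muscle_parameters("bad", "", f_max = -1, l_opt = 0.1, l_ts = 0.1),
               "f_max")
  expect_error(muscle_parameters("bad", "", f_max = 10, l_opt = 0, l_ts = 0.1),
               "l_opt")
  expect_error(muscle_parameters("bad", "", f_max = 10, l_opt = 0.1, l_ts = -0.01),
               "l_ts")
  expect_error(muscle_parameters("bad", "", f_max = 10, l_opt = 0.1, l_ts = 0,
                                 pennation = 95), "pennation")
  expect_error(body_segment("b", mass = -1), "mass")
  expect_error(body_segment("b", mass = 1, inertia = matrix(rnorm(9), 3, 3)),
               "symmetric")
  expect_error(model_coordinate("c", default = 2, range = c(-1, 1)), "range")
  expect_error(wrap_surface("w", "sphere", "b", radii = -0.1), "radii")
  expect_error(model_marker("mk", "b", c(0, 0, 0), weight = -1), "weight")
})

test_that("model assembly validates the joint tree and references", {
  m <- builtin_thoracoscapular_model()
  # muscle referencing a missing body
  bad <- m$muscles
  bad[[1]]$path$points$body[1] <- "no_such_body"
  expect_error(
    shoulder_model("x", m$bodies, m$joints, m$coordinates, bad, m$wraps,
                   m$markers),
    "unknown body")
  # cycle / disconnection
  joints <- m$joints
  joints[[2]]$parent <- "scapula" # defined later than clavicle -> unordered
  expect_error(
    shoulder_model("x", m$bodies, joints, m$coordinates, m$muscles, m$wraps,
                   m$markers),
    "not yet defined")
})

test_that("muscle grouping separates thoracoscapular from glenohumeral", {
  m <- builtin_thoracoscapular_model()
  g <- muscle_groups(m)
  expect_identical(g$group[g$muscle == "Trapezius.ScapulaSuperior"],
                   "thoracoscapular")
  expect_identical(g$group[g$muscle == "SerratusAnterior.Inferior"],
                   "thoracoscapular")
  expect_identical(g$group[g$muscle == "Deltoideus.Middle"], "glenohumeral")
  expect_identical(g$group[g$muscle == "Subscapularis.Middle"], "glenohumeral")
  expect_identical(g$group[g$muscle == "TeresMajor"], "glenohumeral")
})

test_that("hand mass option adds the hand-held load", {
  m0 <- builtin_thoracoscapular_model(hand_mass = 0)
  m2 <- builtin_thoracoscapular_model(hand_mass = 2)
  q0 <- default_q(m0)
  dPE <- potential_energy(m2, q0) - potential_energy(m0, q0)
  # hand point height at reference is below the thorax origin
  fr <- forward_kinematics(m0, q0)
  h <- scapsim:::transform_point(fr[[m0$hand_point$body]], m0$hand_point$loc)[2]
  expect_equal(dPE, 2 * 9.81 * h, tolerance = 1e-9)
})
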