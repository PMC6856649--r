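# Small closed-form fixtures used across the unit tests.

# One rigid link on a hinge about z at the ground origin, with one muscle.
# The muscle runs from a fixed ground point to a point on the link; with
# the default geometry its line of action crosses the hinge at a known
# perpendicular distance.
toy_hinge_model <- function(origin = c(-0.2, 0.03, 0),
                            insertion = c(0.2, 0.03, 0),
                            link_mass = 1, com = c(0.15, 0, 0),
                            f_max = 100, l_opt = 0.2, l_ts = 0.1,
                            wrap = NULL, second_muscle = FALSE) {
  muscles <- list(m1 = list(
    params = muscle_parameters("m1", "", f_max, l_opt, l_ts, 0),
    path = muscle_path(data.frame(body = c("ground", "link"),
                                  x = c(origin[1], insertion[1]),
                                  y = c(origin[2], insertion[2]),
                                  z = c(origin[3], insertion[3])),
                       wraps = if (is.null(wrap)) NULL else list("1" = "w1"))))
  if (second_muscle) {
    muscles$m2 <- muscles$m1
    muscles$m2$params <- muscle_parameters("m2", "", f_max, l_opt, l_ts, 0)
  }
  shoulder_model(
    name = "toy_hinge",
    bodies = list(link = body_segment("link", link_mass, com = com,
                                      inertia = diag(3) * 1e-3)),
    joints = list(list(name = "hinge", type = "hinge", parent = "ground",
                       child = "link", parent_offset = diag(4),
                       coords = "theta", params = list(axis = c(0, 0, 1)))),
    coordinates = list(theta = model_coordinate("theta", 0, c(-pi, pi))),
    muscles = muscles,
    wraps = if (is.null(wrap)) list() else list(w1 = wrap),
    markers = list(
      tip = model_marker("tip", "link", c(0.3, 0, 0)),
      mid = model_marker("mid", "link", c(0.15, 0.05, 0)),
      aux = model_marker("aux", "link", c(0.1, -0.04, 0.05))),
    gravity = c(0, -9.81, 0))
}

# gravity pendulum: link com at distance l from hinge, hanging along -y
toy_pendulum_model <- function(l = 0.3, mass = 2) {
  shoulder_model(
    name = "toy_pendulum",
    bodies = list(link = body_segment("link", mass, com = c(0, -l, 0),
                                      inertia = diag(3) * 1e-4)),
    joints = list(list(name = "hinge", type = "hinge", parent = "ground",
                       child = "link", parent_offset = diag(4),
                       coords = "theta", params = list(axis = c(0, 0, 1)))),
    coordinates = list(theta = model_coordinate("theta", 0, c(-pi, pi))),
    gravity = c(0, -9.81, 0))
}

expect_all_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
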