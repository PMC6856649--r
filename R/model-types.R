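# Domain types for the shoulder model: musculotendon parameters, rigid
# bodies, generalized coordinates, wrap surfaces, muscle paths, markers and
# the assembled model. Plain lists with light S3 classes, validated on
# construction, in the style of base-R modelling packages.

#' Musculotendon actuator architecture parameters
#'
#' One row of the built-in muscle table: maximum isometric force, optimal
#' fiber length, tendon slack length and pennation angle, plus bookkeeping
#' about the anatomical bundles the actuator aggregates.
#'
#' @param name actuator identifier, e.g. `"Trapezius.ScapulaSuperior"`.
#' @param group anatomical group label, e.g. `"Scapula superior"`.
#' @param f_max maximum isometric force in newtons (> 0).
#' @param l_opt optimal fiber length in metres (> 0).
#' @param l_ts tendon slack length in metres (>= 0; zero is permitted).
#' @param pennation pennation angle in degrees (0 <= pennation < 90).
#' @param source_bundles free-text provenance of the aggregated bundles.
#' @return An object of class `muscle_parameters`.
#' @export
muscle_parameters <- function(name, group = "", f_max, l_opt, l_ts,
                              pennation = 0, source_bundles = "") {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(f_max) || f_max <= 0)
    stop(sprintf("muscle '%s': f_max must be > 0 (got %g)", name, f_max))
  if (!is.finite(l_opt) || l_opt <= 0)
    stop(sprintf("muscle '%s': l_opt must be > 0 (got %g)", name, l_opt))
  if (!is.finite(l_ts) || l_ts < 0)
    stop(sprintf("muscle '%s': l_ts must be >= 0 (got %g)", name, l_ts))
  if (!is.finite(pennation) || pennation < 0 || pennation >= 90)
    stop(sprintf("muscle '%s': pennation must be in [0, 90) deg", name))
  structure(list(name = name, group = group, f_max = f_max, l_opt = l_opt,
                 l_ts = l_ts, pennation = pennation,
                 source_bundles = source_bundles),
            class = "muscle_parameters")
}

#' Rigid body segment
#'
#' @param name body name.
#' @param mass mass in kg (>= 0).
#' @param com centre of mass, length-3, in the body frame (m).
#' @param inertia 3x3 inertia tensor about the body frame origin axes at the
#'   com (kg m^2); must be symmetric positive-semidefinite.
#' @return An object of class `body_segment`.
#' @export
body_segment <- function(name, mass, com = c(0, 0, 0), inertia = diag(3) * 0) {
  inertia <- matrix(inertia, 3, 3)
  if (mass < 0) stop(sprintf("body '%s': mass must be >= 0", name))
  if (max(abs(inertia - t(inertia))) > 1e-9)
    stop(sprintf("body '%s': inertia must be symmetric", name))
  ev <- eigen((inertia + t(inertia)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9)
    stop(sprintf("body '%s': inertia must be positive-semidefinite", name))
  structure(list(name = name, mass = mass, com = as.numeric(com),
                 inertia = inertia),
            class = "body_segment")
}

#' Generalized coordinate
#'
#' @param name coordinate name.
#' @param default default value (rad for rotational, m for translational).
#' @param range length-2 `c(min, max)` with `min <= default <= max`.
#' @return An object of class `model_coordinate`.
#' @export
model_coordinate <- function(name, default = 0, range = c(-pi, pi)) {
  if (!(range[1] <= default && default <= range[2]))
    stop(sprintf("coordinate '%s': default outside range", name))
  structure(list(name = name, default = default, range = as.numeric(range)),
            class = "model_coordinate")
}

#' Wrap surface
#'
#' An analytic obstacle a muscle segment may wrap over. Pose is the surface
#' frame expressed in the parent body frame.
#'
#' @param name surface name.
#' @param kind one of `"sphere"`, `"cylinder"`, `"ellipsoid"`.
#' @param body parent body name.
#' @param xform 4x4 homogeneous pose of the surface frame in the body frame.
#' @param radii semi-axes in m: length 1 (sphere), `c(r, half_height)`
#'   (cylinder, axis = local z) or length 3 (ellipsoid).
#' @return An object of class `wrap_surface`.
#' @export
wrap_surface <- function(name, kind = c("sphere", "cylinder", "ellipsoid"),
                         body, xform = diag(4), radii) {
  kind <- match.arg(kind)
  if (any(radii <= 0)) stop(sprintf("wrap '%s': all radii must be > 0", name))
  nr <- c(sphere = 1L, cylinder = 2L, ellipsoid = 3L)[[kind]]
  if (length(radii) != nr)
    stop(sprintf("wrap '%s': kind '%s' needs %d radii", name, kind, nr))
  structure(list(name = name, kind = kind, body = body,
                 xform = xform, radii = as.numeric(radii)),
            class = "wrap_surface")
}

#' Muscle path
#'
#' Ordered attachment points (first = origin, last = insertion) with optional
#' wrap-surface references on the segments between consecutive points.
#'
#' @param points data.frame with columns `body`, `x`, `y`, `z` (m, body frame).
#' @param wraps named list mapping segment index (as character, `"1"` is the
#'   origin-to-second-point segment) to a wrap surface name; or `NULL`.
#' @return An object of class `muscle_path`.
#' @export
muscle_path <- function(points, wraps = NULL) {
  if (nrow(points) < 2) stop("a muscle path needs >= 2 attachment points")
  stopifnot(all(c("body", "x", "y", "z") %in% names(points)))
  structure(list(points = points, wraps = wraps), class = "muscle_path")
}

#' Marker definition
#'
#' @param name marker (ISB landmark) name, e.g. `"AA"`, `"TS"`.
#' @param body parent body name.
#' @param loc length-3 location in the body frame (m).
#' @param weight nonnegative inverse-kinematics weight.
#' @return An object of class `model_marker`.
#' @export
model_marker <- function(name, body, loc, weight = 1) {
  if (weight < 0) stop(sprintf("marker '%s': weight must be >= 0", name))
  structure(list(name = name, body = body, loc = as.numeric(loc),
                 weight = weight),
            class = "model_marker")
}

#' Assemble a shoulder model
#'
#' Validates that the joint set forms a connected acyclic tree rooted at
#' `"ground"` and that every muscle attachment, wrap surface and marker
#' references an existing body.
#'
#' @param name model name.
#' @param bodies named list of [body_segment()] objects.
#' @param joints named list of joints (see Details).
#' @param coordinates named list of [model_coordinate()] objects; the list
#'   order defines the layout of the generalized-coordinate vector `q`.
#' @param muscles named list, each element `list(params =, path =)`.
#' @param wraps named list of [wrap_surface()] objects.
#' @param markers named list of [model_marker()] objects.
#' @param gravity gravity vector in the ground frame, m/s^2.
#' @param hand_mass point mass (kg) welded at `hand_point` (a hand-held load).
#' @param hand_point `list(body =, loc =)` attachment of the hand mass.
#'
#' @details A joint is a list with fields `name`, `type` (one of `"weld"`,
#' `"hinge"`, `"ball"`, `"ellipsoid"`), `parent`, `child`, `parent_offset`
#' (4x4 pose of the joint frame in the parent body frame), `coords`
#' (character vector of coordinate names consumed, in order) and `params`
#' (type-specific: `axis` for hinge; `radii` for the scapulothoracic
#' ellipsoid). Joints must be listed parent-before-child.
#'
#' @return An object of class `shoulder_model`.
#' @export
shoulder_model <- function(name, bodies, joints, coordinates, muscles = list(),
                           wraps = list(), markers = list(),
                           gravity = c(0, -9.81, 0),
                           hand_mass = 0, hand_point = NULL) {
  body_names <- names(bodies)
  known <- "ground"
  for (j in joints) {
    if (!(j$parent %in% known))
      stop(sprintf("joint '%s': parent '%s' not yet defined (tree must be ordered, connected, acyclic)",
                   j$name, j$parent))
    if (j$child %in% known)
      stop(sprintf("joint '%s': child '%s' already attached (cycle)", j$name, j$child))
    if (!(j$child %in% body_names))
      stop(sprintf("joint '%s': unknown child body '%s'", j$name, j$child))
    known <- c(known, j$child)
  }
  unattached <- setdiff(body_names, known)
  if (length(unattached))
    stop("bodies not attached to the joint tree: ", paste(unattached, collapse = ", "))
  for (m in muscles) {
    bad <- setdiff(unique(m$path$points$body), c(body_names, "ground"))
    if (length(bad))
      stop(sprintf("muscle '%s' references unknown body: %s",
                   m$params$name, paste(bad, collapse = ", ")))
  }
  for (w in wraps) if (!(w$body %in% c(body_names, "ground")))
    stop(sprintf("wrap '%s' references unknown body '%s'", w$name, w$body))
  for (mk in markers) if (!(mk$body %in% c(body_names, "ground")))
    stop(sprintf("marker '%s' references unknown body '%s'", mk$name, mk$body))
  coord_in_joints <- unlist(lapply(joints, `[[`, "coords"))
  if (!setequal(coord_in_joints, names(coordinates)))
    stop("coordinate list does not match the coordinates consumed by joints")
  structure(list(name = name, bodies = bodies, joints = joints,
                 coordinates = coordinates, muscles = muscles, wraps = wraps,
                 markers = markers, gravity = as.numeric(gravity),
                 hand_mass = hand_mass, hand_point = hand_point),
            class = "shoulder_model")
}

#' @export
print.shoulder_model <- function(x, ...) {
  cat(sprintf("<shoulder_model '%s'>\n", x$name))
  cat(sprintf("  bodies: %d  joints: %d  coordinates: %d\n",
              length(x$bodies), length(x$joints), length(x$coordinates)))
  cat(sprintf("  muscles: %d  wrap surfaces: %d  markers: %d\n",
              length(x$muscles), length(x$wraps), length(x$markers)))
  if (x$hand_mass > 0)
    cat(sprintf("  hand-held mass: %.3g kg on '%s'\n", x$hand_mass,
                x$hand_point$body))
  invisible(x)
}

#' Names and defaults of the model's generalized coordinates
#'
#' @param model a [shoulder_model()].
#' @return `coord_names`: character vector in `q`-vector order.
#' @export
coord_names <- function(model) names(model$coordinates)

#' @rdname coord_names
#' @return `default_q`: named numeric vector of coordinate defaults.
#' @export
default_q <- function(model) {
  q <- vapply(model$coordinates, `[[`, numeric(1), "default")
  names(q) <- names(model$coordinates)
  q
}

#' @rdname coord_names
#' @return `coord_ranges`: 2-column matrix of coordinate ranges (min, max).
#' @export
coord_ranges <- function(model) {
  r <- t(vapply(model$coordinates, `[[`, numeric(2), "range"))
  colnames(r) <- c("min", "max")
  r
}

#' @keywords internal
check_q <- function(model, q, enforce_range = FALSE) {
  cn <- coord_names(model)
  if (length(q) != length(cn))
    stop(sprintf("q has length %d, model has %d coordinates", length(q), length(cn)))
  if (enforce_range) {
    r <- coord_ranges(model)
    bad <- which(q < r[, 1] - 1e-12 | q > r[, 2] + 1e-12)
    if (length(bad))
      stop(sprintf("coordinate '%s' = %.4g outside range [%.4g, %.4g]",
                   cn[bad[1]], q[bad[1]], r[bad[1], 1], r[bad[1], 2]))
  }
  stats::setNames(as.numeric(q), cn)
}
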