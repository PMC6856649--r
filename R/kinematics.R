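# Forward kinematics: joint transforms composed along the body tree, with
# the scapulothoracic ellipsoid joint as the centerpiece.

#' Scapulothoracic joint transform
#'
#' Pose of the scapula frame in the ellipsoid (joint) frame for coordinates
#' `q_st = (abduction, elevation, upward_rotation, winging)`, all in radians.
#'
#' Abduction and elevation are surface angles locating the scapula contact
#' point through the trigonometric parameterization of the ellipsoid
#' `p = (rx sin(a) cos(e), ry sin(e), rz cos(a) cos(e))`, which lies on the
#' surface for every (a, e) by construction. Upward rotation acts about the
#' outward surface normal at the contact point; winging acts about the
#' surface tangent along the elevation direction (the scapular medial
#' border). The scapula frame origin is the contact point, so for
#' `winging = 0` the origin satisfies the implicit ellipsoid equation
#' exactly.
#'
#' @param radii length-3 ellipsoid semi-axes (m).
#' @param q_st length-4 joint coordinates (rad).
#' @return 4x4 homogeneous transform (scapula frame in ellipsoid frame).
#' @seealso [scapula_contact_jacobian()]
#' @export
scapula_transform <- function(radii, q_st) {
  a <- q_st[1]; e <- q_st[2]; u <- q_st[3]; w <- q_st[4]
  rx <- radii[1]; ry <- radii[2]; rz <- radii[3]
  sa <- sin(a); ca <- cos(a); se <- sin(e); ce <- cos(e)
  p <- c(rx * sa * ce, ry * se, rz * ca * ce)
  # elevation tangent dP/de (normalized) and outward normal
  te <- c(-rx * sa * se, ry * ce, -rz * ca * se)
  te <- te / sqrt(sum(te^2))
  n <- c(sa * ce / rx, se / ry, ca * ce / rz)
  n <- n / sqrt(sum(n^2))
  b <- cross3(n, te)
  F <- cbind(te, b, n) # local x = medial-border tangent, z = outward normal
  R <- F %*% rot_z(u) %*% rot_x(w)
  make_transform(R, p)
}

#' Analytic Jacobian of the scapulothoracic contact point
#'
#' Closed-form partial derivatives of the scapula frame origin (the contact
#' point) with respect to the four joint coordinates, in the ellipsoid frame.
#' The origin depends only on abduction and elevation, so the last two
#' columns are zero. Used to validate the geometry against central
#' differences and by the inverse-kinematics solver tests.
#'
#' @inheritParams scapula_transform
#' @return 3x4 Jacobian matrix d(contact point)/d(q_st).
#' @export
scapula_contact_jacobian <- function(radii, q_st) {
  a <- q_st[1]; e <- q_st[2]
  rx <- radii[1]; ry <- radii[2]; rz <- radii[3]
  sa <- sin(a); ca <- cos(a); se <- sin(e); ce <- cos(e)
  cbind(c(rx * ca * ce, 0, -rz * sa * ce),
        c(-rx * sa * se, ry * ce, -rz * ca * se),
        c(0, 0, 0), c(0, 0, 0))
}

#' @keywords internal
joint_variable_transform <- function(joint, qj, frames = NULL, parent_T = NULL) {
  switch(joint$type,
    weld = diag(4),
    hinge = make_transform(rot_axis(joint$params$axis, qj[1])),
    ball = {
      # elevation-plane convention: plane angle about y, elevation about the
      # rotated z, then axial rotation about the (rotated-back) long axis y.
      make_transform(rot_y(qj[1]) %*% rot_z(qj[2]) %*% rot_y(qj[3] - qj[1]))
    },
    ellipsoid = scapula_transform(joint$params$radii, qj),
    aim = {
      # zero-DOF follower: rotates the child so its reference aim direction
      # points at a target point on another (already-posed) body; used for
      # the clavicle, whose lateral end rides on the scapula's acromion.
      tgt <- transform_point(frames[[joint$params$target_body]],
                             joint$params$target_point)
      jw <- parent_T %*% joint$parent_offset
      u1 <- drop(t(jw[1:3, 1:3]) %*% (tgt - jw[1:3, 4])) # target, joint frame
      u0 <- joint$params$aim_ref
      u0 <- u0 / sqrt(sum(u0^2)); u1 <- u1 / sqrt(sum(u1^2))
      ax <- cross3(u0, u1)
      s <- sqrt(sum(ax^2)); cth <- sum(u0 * u1)
      R <- if (s < 1e-12) diag(3) else rot_axis(ax / s, atan2(s, cth))
      make_transform(R)
    },
    stop(sprintf("unknown joint type '%s'", joint$type))
  )
}

#' Forward kinematics of the whole model
#'
#' Composes joint transforms along the body tree and returns each body's
#' frame expressed in ground.
#'
#' @param model a [shoulder_model()].
#' @param q named or ordered numeric vector of generalized coordinates.
#' @param check_range error if any coordinate is outside its stated range.
#' @return Named list of 4x4 transforms, one per body (plus `"ground"`).
#' @export
forward_kinematics <- function(model, q, check_range = FALSE) {
  q <- check_q(model, q, enforce_range = check_range)
  frames <- vector("list", length(model$bodies) + 1L)
  names(frames) <- c("ground", names(model$bodies))
  frames[["ground"]] <- diag(4)
  for (j in model$joints) {
    qj <- if (length(j$coords)) q[j$coords] else numeric(0)
    frames[[j$child]] <- frames[[j$parent]] %*% j$parent_offset %*%
      joint_variable_transform(j, qj, frames, frames[[j$parent]])
  }
  frames
}

#' World positions of the model markers at a pose
#'
#' @inheritParams forward_kinematics
#' @param frames optional precomputed output of [forward_kinematics()].
#' @return n_markers x 3 matrix with marker names as row names.
#' @export
marker_positions <- function(model, q, frames = NULL) {
  if (is.null(frames)) frames <- forward_kinematics(model, q)
  out <- matrix(NA_real_, length(model$markers), 3,
                dimnames = list(names(model$markers), c("x", "y", "z")))
  for (i in seq_along(model$markers)) {
    mk <- model$markers[[i]]
    out[i, ] <- transform_point(frames[[mk$body]], mk$loc)
  }
  out
}

#' Surface residual of the scapulothoracic contact constraint
#'
#' `|(x/rx)^2 + (y/ry)^2 + (z/rz)^2 - 1|` evaluated at the scapula frame
#' origin in the ellipsoid frame. Zero (to round-off) whenever winging = 0.
#'
#' @inheritParams scapula_transform
#' @return nonnegative scalar residual.
#' @export
scapula_surface_residual <- function(radii, q_st) {
  p <- scapula_transform(radii, q_st)[1:3, 4]
  abs(sum((p / radii)^2) - 1)
}
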