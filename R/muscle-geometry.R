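# Muscle path lengths over wrap surfaces and tendon-excursion moment arms.
#
# Sphere and cylinder wraps are solved in closed form (tangent-arc-tangent);
# the ellipsoid wrap is solved numerically as the shortest polyline that does
# not penetrate the quadric (projected "rubber band" relaxation, coarse-to-
# fine). When a segment merely grazes a surface the straight segment is used
# (zero-arc limit), which keeps path length continuous in the coordinates.

#' Shortest muscle-path segment over a wrap surface
#'
#' Both endpoints are expressed in the *surface frame* (centered,
#' axis-aligned; cylinder axis = local z). Returns the shortest smooth path
#' from `p1` to `p2` that does not penetrate the surface; when the straight
#' segment misses the surface it is returned unchanged.
#'
#' @param p1,p2 length-3 endpoints in the surface frame (m), both outside the
#'   surface.
#' @param surface a [wrap_surface()] (its pose is ignored here; callers
#'   transform the endpoints).
#' @param n_points polyline resolution for the numeric ellipsoid solve.
#' @param tol convergence tolerance (m) on the ellipsoid path length.
#' @param max_iter relaxation iteration cap per refinement level.
#' @param init optional n x 3 matrix of path points to warm-start the
#'   ellipsoid solve (e.g. the solution at a neighbouring pose).
#' @return A `path_solution`: list with `points` (n x 3 in the surface
#'   frame), `length` (m) and `wrapped` (logical).
#' @export
wrap_over_surface <- function(p1, p2, surface, n_points = 33,
                              tol = 1e-9, max_iter = 800, init = NULL) {
  kind <- surface$kind
  radii <- surface$radii
  if (.inside_surface(p1, surface) || .inside_surface(p2, surface))
    stop(sprintf("wrap path undefined: endpoint inside wrap surface '%s'",
                 surface$name), call. = FALSE)
  sol <- switch(kind,
    sphere = .wrap_sphere(p1, p2, radii[1]),
    cylinder = .wrap_cylinder(p1, p2, radii[1]),
    ellipsoid = .wrap_ellipsoid(p1, p2, radii, n_points, tol, max_iter, init))
  structure(sol, class = "path_solution")
}

#' @keywords internal
.inside_surface <- function(p, surface) {
  r <- surface$radii
  switch(surface$kind,
    sphere = sum(p^2) < r[1]^2 * (1 - 1e-12),
    cylinder = sum(p[1:2]^2) < r[1]^2 * (1 - 1e-12) && abs(p[3]) < r[2],
    ellipsoid = sum((p / r)^2) < 1 - 1e-12)
}

# closed-form sphere wrap in the plane through p1, p2 and the centre
.wrap_sphere <- function(p1, p2, r) {
  d1 <- sqrt(sum(p1^2)); d2 <- sqrt(sum(p2^2))
  straight <- list(points = rbind(p1, p2),
                   length = sqrt(sum((p2 - p1)^2)), wrapped = FALSE)
  # does the straight segment cross the sphere interior?
  v <- p2 - p1; L2 <- sum(v^2)
  t <- if (L2 > 0) max(0, min(1, -sum(p1 * v) / L2)) else 0
  closest <- p1 + t * v
  if (sqrt(sum(closest^2)) >= r * (1 - 1e-12) || t <= 0 || t >= 1)
    return(straight)
  th12 <- acos(max(-1, min(1, sum(p1 * p2) / (d1 * d2))))
  b1 <- acos(max(-1, min(1, r / d1)))
  b2 <- acos(max(-1, min(1, r / d2)))
  phi <- th12 - b1 - b2
  if (phi <= 0) return(straight) # grazing: zero-arc limit
  lt1 <- sqrt(max(0, d1^2 - r^2)); lt2 <- sqrt(max(0, d2^2 - r^2))
  # tangent points in the wrap plane
  e1 <- p1 / d1
  e2p <- p2 - sum(p2 * e1) * e1
  e2 <- e2p / sqrt(sum(e2p^2))
  ang1 <- b1
  ang2 <- th12 - b2
  arc_ang <- seq(ang1, ang2, length.out = 33)
  arc <- t(vapply(arc_ang, function(a) r * (cos(a) * e1 + sin(a) * e2),
                  numeric(3)))
  list(points = rbind(p1, arc, p2),
       length = lt1 + r * phi + lt2, wrapped = TRUE)
}

# cylinder wrap: 2D circle wrap in the cross-section, axial coordinate
# distributed linearly in planar arc length (the unrolled geodesic).
.wrap_cylinder <- function(p1, p2, r) {
  q1 <- p1[1:2]; q2 <- p2[1:2]
  straight <- list(points = rbind(p1, p2),
                   length = sqrt(sum((p2 - p1)^2)), wrapped = FALSE)
  v <- q2 - q1; L2 <- sum(v^2)
  t <- if (L2 > 0) max(0, min(1, -sum(q1 * v) / L2)) else 0
  if (sqrt(sum((q1 + t * v)^2)) >= r * (1 - 1e-12) || t <= 0 || t >= 1)
    return(straight)
  d1 <- sqrt(sum(q1^2)); d2 <- sqrt(sum(q2^2))
  th12 <- acos(max(-1, min(1, sum(q1 * q2) / (d1 * d2))))
  b1 <- acos(max(-1, min(1, r / d1)))
  b2 <- acos(max(-1, min(1, r / d2)))
  phi <- th12 - b1 - b2
  if (phi <= 0) return(straight)
  lt1 <- sqrt(max(0, d1^2 - r^2)); lt2 <- sqrt(max(0, d2^2 - r^2))
  planar <- lt1 + r * phi + lt2
  len <- sqrt(planar^2 + (p2[3] - p1[3])^2)
  e1 <- q1 / d1
  e2p <- q2 - sum(q2 * e1) * e1
  e2 <- e2p / sqrt(sum(e2p^2))
  arc_ang <- seq(b1, th12 - b2, length.out = 33)
  s_axial <- lt1 + r * (arc_ang - b1) # planar arc length at each arc point
  z <- p1[3] + (p2[3] - p1[3]) * s_axial / planar
  arc <- cbind(t(vapply(arc_ang, function(a) r * (cos(a) * e1 + sin(a) * e2),
                        numeric(2))), z)
  list(points = rbind(p1, arc, p2), length = len, wrapped = TRUE)
}

# numeric ellipsoid wrap: projected rubber-band relaxation, coarse-to-fine
.wrap_ellipsoid <- function(p1, p2, radii, n_points, tol, max_iter, init) {
  straight <- list(points = rbind(p1, p2),
                   length = sqrt(sum((p2 - p1)^2)), wrapped = FALSE)
  if (!.segment_hits_ellipsoid(p1, p2, radii)) return(straight)

  if (!is.null(init) && nrow(init) >= 5) {
    # warm start at full resolution from a neighbouring solution
    P <- .resample_polyline(init, n_points)
    P[1, ] <- p1; P[nrow(P), ] <- p2
    P <- .push_outside(P, radii)
    P <- .relax_rubber_band(P, radii, tol, max_iter)
  } else {
    # cold start: coarse-to-fine keeps the relaxation cheap
    P <- .resample_polyline(rbind(p1, p2), 9)
    P <- .push_outside(P, radii)
    sizes <- c(9, 17, 33, 65, 129, 257)
    sizes <- sizes[sizes <= n_points]
    if (!length(sizes) || sizes[length(sizes)] != n_points)
      sizes <- c(sizes, n_points)
    for (n in sizes) {
      P <- .resample_polyline(P, n)
      P <- .push_outside(P, radii)
      P <- .relax_rubber_band(P, radii, tol, max_iter)
    }
  }
  len <- sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
  wrapped <- len > straight$length + 1e-12
  if (!wrapped) return(straight)
  list(points = P, length = len, wrapped = TRUE)
}

#' @keywords internal
.segment_hits_ellipsoid <- function(p1, p2, radii) {
  a <- p1 / radii; b <- p2 / radii # sphere of radius 1 after scaling
  v <- b - a; L2 <- sum(v^2)
  t <- if (L2 > 0) max(0, min(1, -sum(a * v) / L2)) else 0
  if (t <= 0 || t >= 1) return(FALSE)
  sum((a + t * v)^2) < 1 - 1e-12
}

#' @keywords internal
.resample_polyline <- function(P, n) {
  P <- matrix(P, ncol = 3)
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(matrix(rep(P[1, ], n), n, 3, byrow = TRUE))
  si <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, P[, 1], si)$y,
        stats::approx(s, P[, 2], si)$y,
        stats::approx(s, P[, 3], si)$y)
}

#' Vectorized orthogonal projection of points onto an ellipsoid
#'
#' Newton iteration on the Lagrange multiplier, applied simultaneously to
#' all rows of `P` (intended for points near the surface, where Newton from
#' t = 0 converges in a handful of steps).
#'
#' @keywords internal
.project_points_ellipsoid <- function(P, radii) {
  r2 <- radii^2
  x1 <- P[, 1]; x2 <- P[, 2]; x3 <- P[, 3]
  t <- numeric(nrow(P))
  tmin <- -min(r2) * 0.99
  for (it in 1:30) {
    d1 <- r2[1] + t; d2 <- r2[2] + t; d3 <- r2[3] + t
    f <- (x1 * radii[1] / d1)^2 + (x2 * radii[2] / d2)^2 +
      (x3 * radii[3] / d3)^2 - 1
    if (all(abs(f) < 1e-13)) break
    fp <- -2 * ((x1^2 * r2[1]) / d1^3 + (x2^2 * r2[2]) / d2^3 +
                  (x3^2 * r2[3]) / d3^3)
    t <- pmax(t - f / fp, tmin)
  }
  cbind(x1 * r2[1] / (r2[1] + t), x2 * r2[2] / (r2[2] + t),
        x3 * r2[3] / (r2[3] + t))
}

#' @keywords internal
.push_outside <- function(P, radii) {
  n <- nrow(P)
  if (n <= 2) return(P)
  idx <- 2:(n - 1)
  f <- (P[idx, 1] / radii[1])^2 + (P[idx, 2] / radii[2])^2 +
    (P[idx, 3] / radii[3])^2
  inside <- which(f < 1)
  if (length(inside))
    P[idx[inside], ] <- .project_points_ellipsoid(
      P[idx[inside], , drop = FALSE], radii)
  P
}

# red-black Gauss-Seidel relaxation of the constrained shortest path: each
# interior point moves to the midpoint of its neighbours (locally shortest)
# and is projected back onto the surface if that takes it inside.
#' @keywords internal
.relax_rubber_band <- function(P, radii, tol, max_iter) {
  n <- nrow(P)
  if (n <= 2) return(P)
  r1 <- radii[1]; r2 <- radii[2]; r3 <- radii[3]
  interior <- 2:(n - 1)
  odd <- interior[interior %% 2 == 0]
  even <- interior[interior %% 2 == 1]
  half_step <- function(idx) {
    mid <- (P[idx - 1, , drop = FALSE] + P[idx + 1, , drop = FALSE]) / 2
    f <- (mid[, 1] / r1)^2 + (mid[, 2] / r2)^2 + (mid[, 3] / r3)^2
    inside <- which(f < 1)
    if (length(inside))
      mid[inside, ] <- .project_points_ellipsoid(mid[inside, , drop = FALSE],
                                                 radii)
    P[idx, ] <<- mid
  }
  move_check <- max(8L, n %/% 4)
  Pref <- P
  for (it in seq_len(max_iter)) {
    half_step(odd)
    half_step(even)
    if (it %% move_check == 0) {
      if (max(abs(P - Pref)) < tol) break
      Pref <- P
    }
  }
  P
}

#' Musculotendon path length at a pose
#'
#' Sum of straight segments and wrap arcs of a muscle's path. Continuous in
#' the coordinates; errors if a wrapped segment has an endpoint inside its
#' wrap surface (the undefined-path condition), naming the muscle and
#' surface.
#'
#' @param model a [shoulder_model()].
#' @param q generalized coordinates.
#' @param muscle muscle name.
#' @param frames optional precomputed [forward_kinematics()] output.
#' @param detail if `TRUE`, return a list with per-segment information
#'   instead of just the length.
#' @param cache optional environment used to warm-start numeric wrap solves
#'   from the previous call (per muscle/segment); speeds up sweeps,
#'   finite-difference moment arms and tracking loops.
#' @return Length in metres (or a list when `detail = TRUE`).
#' @export
path_length <- function(model, q, muscle, frames = NULL, detail = FALSE,
                        cache = NULL) {
  mus <- model$muscles[[muscle]]
  if (is.null(mus)) stop(sprintf("unknown muscle '%s'", muscle))
  if (is.null(frames)) frames <- forward_kinematics(model, q)
  pts <- mus$path$points
  W <- matrix(NA_real_, nrow(pts), 3)
  for (i in seq_len(nrow(pts)))
    W[i, ] <- transform_point(frames[[pts$body[i]]], c(pts$x[i], pts$y[i], pts$z[i]))
  total <- 0
  segs <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    wname <- if (!is.null(mus$path$wraps)) mus$path$wraps[[as.character(i)]] else NULL
    if (is.null(wname)) {
      L <- sqrt(sum((W[i + 1, ] - W[i, ])^2))
      segs[[i]] <- list(wrapped = FALSE, length = L)
    } else {
      surf <- model$wraps[[wname]]
      Tw <- frames[[surf$body]] %*% surf$xform
      Tw_inv <- transform_inverse(Tw)
      key <- paste0(muscle, "#", i)
      init <- if (!is.null(cache)) cache[[key]] else NULL
      # warm starts run a fixed short relaxation: deterministic, smooth in
      # the pose, and cheap inside finite-difference and tracking loops
      sol <- tryCatch(
        wrap_over_surface(transform_point(Tw_inv, W[i, ]),
                          transform_point(Tw_inv, W[i + 1, ]), surf,
                          init = init,
                          tol = if (is.null(init)) 1e-9 else 0,
                          max_iter = if (is.null(init)) 400 else 40),
        error = function(e)
          stop(sprintf("muscle '%s', segment %d: %s", muscle, i,
                       conditionMessage(e)), call. = FALSE))
      if (!is.null(cache) && surf$kind == "ellipsoid")
        cache[[key]] <- if (sol$wrapped) sol$points else NULL
      L <- sol$length
      segs[[i]] <- list(wrapped = sol$wrapped, length = L, surface = wname)
    }
    total <- total + L
  }
  if (!detail) return(total)
  list(length = total, segments = segs, points = W)
}

#' Path lengths of all muscles at a pose
#'
#' @inheritParams path_length
#' @param muscles optional subset of muscle names.
#' @return Named numeric vector of musculotendon lengths (m).
#' @export
muscle_lengths <- function(model, q, frames = NULL, muscles = NULL,
                           cache = NULL) {
  if (is.null(frames)) frames <- forward_kinematics(model, q)
  if (is.null(muscles)) muscles <- names(model$muscles)
  vapply(muscles, function(m) path_length(model, q, m, frames, cache = cache),
         numeric(1))
}

#' Coordinates that can affect each muscle's length
#'
#' Structural dependency map: the coordinates of the joints on the tree
#' path between any pair of bodies a muscle's path (or its wrap surfaces)
#' touches. Used to skip finite-difference work for coordinate/muscle pairs
#' whose moment arm is structurally zero.
#'
#' @param model a [shoulder_model()].
#' @return named list: muscle -> character vector of coordinate names.
#' @export
muscle_coord_dependencies <- function(model) {
  parent_of <- list()
  joint_of <- list()
  for (j in model$joints) { parent_of[[j$child]] <- j$parent; joint_of[[j$child]] <- j }
  # full set of coordinates a body's world pose depends on (joints are
  # listed parent-first, so affect[] of ancestors and aim targets is ready)
  affect <- list(ground = character(0))
  aim_coupled <- c(ground = FALSE)
  for (j in model$joints) {
    a <- c(affect[[j$parent]], j$coords)
    coupled <- aim_coupled[[j$parent]]
    if (j$type == "aim") {
      a <- c(a, affect[[j$params$target_body]])
      coupled <- TRUE
    }
    affect[[j$child]] <- unique(a)
    aim_coupled[[j$child]] <- coupled
  }
  root_path <- function(b) {
    out <- character(0)
    while (b != "ground") { out <- c(out, b); b <- parent_of[[b]] }
    out
  }
  coords_between <- function(b1, b2) {
    # when an aim-coupled body is involved, the relative pose can depend on
    # every coordinate either body sees; fall back to the union
    if (isTRUE(aim_coupled[[b1]]) || isTRUE(aim_coupled[[b2]]))
      return(unique(c(affect[[b1]], affect[[b2]])))
    p1 <- root_path(b1); p2 <- root_path(b2)
    diff_bodies <- c(setdiff(p1, p2), setdiff(p2, p1))
    unique(unlist(lapply(diff_bodies, function(b) joint_of[[b]]$coords)))
  }
  out <- list()
  for (mname in names(model$muscles)) {
    mus <- model$muscles[[mname]]
    bodies <- unique(mus$path$points$body)
    if (!is.null(mus$path$wraps))
      bodies <- unique(c(bodies, vapply(mus$path$wraps, function(w)
        model$wraps[[w]]$body, character(1))))
    cs <- character(0)
    if (length(bodies) > 1)
      for (a in seq_along(bodies)) for (b in seq_len(a - 1))
        cs <- unique(c(cs, coords_between(bodies[a], bodies[b])))
    out[[mname]] <- cs
  }
  out
}

#' Tendon-excursion moment arm
#'
#' `r = -dL/dq` by central difference (default step 1e-5 rad). Positive `r`
#' means the muscle generates a positive generalized force on the
#' coordinate.
#'
#' @inheritParams path_length
#' @param coord coordinate name (rotational).
#' @param h central-difference step (rad).
#' @return Moment arm in metres.
#' @export
moment_arm <- function(model, q, muscle, coord, h = 1e-5) {
  q <- check_q(model, q)
  iq <- match(coord, coord_names(model))
  if (is.na(iq)) stop(sprintf("unknown coordinate '%s'", coord))
  qp <- q; qp[iq] <- qp[iq] + h
  qm <- q; qm[iq] <- qm[iq] - h
  -(path_length(model, qp, muscle) - path_length(model, qm, muscle)) / (2 * h)
}

#' Moment-arm matrix of all muscles over all coordinates
#'
#' Structurally-zero entries (muscle does not cross the coordinate's joint)
#' are skipped via [muscle_coord_dependencies()].
#'
#' @inheritParams moment_arm
#' @param deps optional precomputed [muscle_coord_dependencies()] map.
#' @param cache optional wrap warm-start environment (see [path_length()]).
#' @return n_coords x n_muscles matrix `R` with `R[j, i] = -dL_i/dq_j`.
#' @export
moment_arm_matrix <- function(model, q, h = 1e-5, deps = NULL, cache = NULL) {
  q <- check_q(model, q)
  cn <- coord_names(model)
  mn <- names(model$muscles)
  if (is.null(deps)) deps <- muscle_coord_dependencies(model)
  R <- matrix(0, length(cn), length(mn), dimnames = list(cn, mn))
  for (j in seq_along(cn)) {
    act <- mn[vapply(mn, function(m) cn[j] %in% deps[[m]], logical(1))]
    if (!length(act)) next
    qp <- q; qp[j] <- qp[j] + h
    qm <- q; qm[j] <- qm[j] - h
    Lp <- muscle_lengths(model, qp, muscles = act, cache = cache)
    Lm <- muscle_lengths(model, qm, muscles = act, cache = cache)
    R[j, act] <- -(Lp - Lm) / (2 * h)
  }
  R
}

#' Fiber operating-range report over a motion
#'
#' Rigid-tendon normalized fiber length `l_fiber / l_opt` of each muscle over
#' a coordinate trajectory; muscles leaving the [0.5, 1.5] operating range
#' are flagged (too short to produce force, or overstretched).
#'
#' @param model a [shoulder_model()].
#' @param q_traj n_frames x n_coords matrix of coordinates.
#' @param lo,hi operating-range bounds on `l_fiber / l_opt`.
#' @return data.frame with columns `muscle`, `min_ratio`, `max_ratio`,
#'   `flag_low`, `flag_high`.
#' @export
check_fiber_operating_range <- function(model, q_traj, lo = 0.5, hi = 1.5) {
  q_traj <- matrix(q_traj, ncol = length(coord_names(model)))
  mn <- names(model$muscles)
  ratios <- matrix(NA_real_, nrow(q_traj), length(mn))
  wcache <- new.env(parent = emptyenv())
  for (f in seq_len(nrow(q_traj))) {
    L <- muscle_lengths(model, q_traj[f, ], cache = wcache)
    for (i in seq_along(mn)) {
      p <- model$muscles[[i]]$params
      fk <- fiber_kinematics(p, L[i], 0)
      ratios[f, i] <- fk$l_fiber / p$l_opt
    }
  }
  data.frame(muscle = mn,
             min_ratio = apply(ratios, 2, min),
             max_ratio = apply(ratios, 2, max),
             flag_low = apply(ratios, 2, min) < lo,
             flag_high = apply(ratios, 2, max) > hi,
             stringsAsFactors = FALSE)
}

#' Tune fiber/tendon lengths of out-of-range muscles
#'
#' For each flagged muscle, iteratively increases optimal fiber length by 2%
#' and reduces tendon slack length by the same absolute amount until the
#' muscle's normalized fiber length lies in the operating range over the
#' motion, or the tendon slack length would go negative (then clamped at 0
#' and iteration stops for that muscle). Every step is logged.
#'
#' @inheritParams check_fiber_operating_range
#' @param max_iter iteration cap per muscle; exceeding it raises an error
#'   listing the unconverged muscles.
#' @return list with `model` (updated), `log` (data.frame of steps) and
#'   `unresolved` (muscles clamped but still flagged).
#' @export
tune_muscle_lengths <- function(model, q_traj, lo = 0.5, hi = 1.5,
                                max_iter = 100) {
  q_traj <- matrix(q_traj, ncol = length(coord_names(model)))
  log_rows <- list()
  unresolved <- character(0)
  failed <- character(0)
  # musculotendon lengths do not depend on the architecture parameters,
  # so compute them once
  wcache <- new.env(parent = emptyenv())
  Lmat <- t(apply(q_traj, 1, function(qr) muscle_lengths(model, qr, cache = wcache)))
  Lmat <- matrix(Lmat, nrow = nrow(q_traj))
  for (i in seq_along(model$muscles)) {
    p <- model$muscles[[i]]$params
    Ls <- Lmat[, i]
    ratio_range <- function(p) {
      lf <- pmax(Ls - p$l_ts, 0) / cos(p$pennation * pi / 180)
      range(lf / p$l_opt)
    }
    it <- 0
    clamped <- FALSE
    repeat {
      rr <- ratio_range(p)
      in_range <- rr[1] >= lo && rr[2] <= hi
      if (in_range || clamped) break
      it <- it + 1
      if (it > max_iter) { failed <- c(failed, p$name); break }
      delta <- 0.02 * p$l_opt
      new_lts <- p$l_ts - delta
      if (new_lts < 0) { new_lts <- 0; clamped <- TRUE }
      log_rows[[length(log_rows) + 1]] <- data.frame(
        muscle = p$name, iter = it, l_opt_old = p$l_opt,
        l_opt_new = p$l_opt + delta, l_ts_old = p$l_ts, l_ts_new = new_lts,
        clamped = clamped, stringsAsFactors = FALSE)
      p$l_opt <- p$l_opt + delta
      p$l_ts <- new_lts
    }
    rr <- ratio_range(p)
    if (clamped && !(rr[1] >= lo && rr[2] <= hi))
      unresolved <- c(unresolved, p$name)
    model$muscles[[i]]$params <- p
  }
  if (length(failed))
    stop("fiber/tendon tuning did not converge within ", max_iter,
         " iterations for: ", paste(failed, collapse = ", "))
  list(model = model,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(muscle = character(0)),
       unresolved = unresolved)
}
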