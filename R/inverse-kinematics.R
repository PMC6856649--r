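# Marker-based inverse kinematics: per-frame damped least squares
# (Levenberg-Marquardt, monotone objective), warm-started across frames for
# temporal coherence, plus calibration of the scapulothoracic ellipsoid.

#' @keywords internal
.ik_residual <- function(model, q, target, weights) {
  # target: n_markers x 3 (rows may be NA = occluded); returns stacked
  # weighted residual vector and the raw per-marker errors
  mp <- marker_positions(model, q)
  diff <- target - mp
  ok <- stats::complete.cases(diff)
  w <- sqrt(weights[ok])
  list(res = as.numeric(t(diff[ok, , drop = FALSE] * w)), visible = ok,
       err = diff)
}

#' @keywords internal
.ik_solve_frame <- function(model, target, weights, q0, ranges,
                            tol = 1e-10, max_iter = 60, h = 1e-6,
                            reg = 1e-5, q_ref = q0) {
  # A tiny Tikhonov prior toward a reference pose keeps coordinates that
  # are momentarily unobservable (e.g. the humeral elevation plane at zero
  # elevation) from wandering into mirror local minima; its pull on
  # well-observed coordinates is orders of magnitude below the marker term.
  q <- q0
  nq <- length(q)
  sr <- sqrt(reg)
  resid <- function(qq) {
    r <- .ik_residual(model, qq, target, weights)
    r$res <- c(r$res, sr * (qq - q_ref))
    r
  }
  r0 <- resid(q)
  f <- sum(r0$res^2)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    # numeric Jacobian of the weighted residual wrt q
    J <- matrix(0, length(r0$res), nq)
    for (i in seq_len(nq)) {
      qp <- q; qp[i] <- qp[i] + h
      qm <- q; qm[i] <- qm[i] - h
      J[, i] <- (resid(qp)$res - resid(qm)$res) / (2 * h)
    }
    g <- crossprod(J, r0$res)
    H <- crossprod(J)
    improved <- FALSE
    for (tries in 1:12) {
      step <- tryCatch(solve(H + lambda * diag(nq), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        qn <- pmin(pmax(q - as.numeric(step), ranges[, 1]), ranges[, 2])
        rn <- resid(qn)
        fn <- sum(rn$res^2)
        # strict decrease only: an equal-objective step is null-space drift
        # (e.g. the gh_plane/gh_rot gimbal pair with the arm hanging), not
        # progress
        if (fn < f) {
          q <- qn; r0 <- rn
          improved <- TRUE
          converged <- (f - fn) < tol
          f <- fn
          lambda <- max(lambda * 0.3, 1e-10)
          if (converged) return(list(q = q, f = f, iters = it))
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) return(list(q = q, f = f, iters = it))
  }
  list(q = q, f = f, iters = max_iter)
}

#' Marker-based inverse kinematics
#'
#' Per frame, finds generalized coordinates minimizing the weighted
#' least-squares marker error `sum_i w_i |m_i_exp - m_i_model(q)|^2`
#' (damped least squares with a monotone objective), warm-starting each
#' frame from the previous solution. Frames with fewer than 3 visible
#' markers are flagged and their coordinates linearly interpolated from
#' neighbouring solved frames.
#'
#' @param model a [shoulder_model()].
#' @param marker_frames either a `trc_data` object from [read_trc()] or a
#'   list with `time` (length n) and `markers` (n x 3 x n_markers array or a
#'   list of n_frames matrices `n_markers x 3` with marker row names).
#' @param weights optional named marker weights; defaults to the model's
#'   marker weights.
#' @param q0 starting pose for the first frame (defaults to the model's
#'   default coordinates).
#' @param tol convergence tolerance on the objective decrease.
#' @return list of class `ik_result`: `time`, `q` (n_frames x n_coords),
#'   `rmse` per frame (m, over visible markers), `rmse_total` (m, over all
#'   frames and markers), `flagged` (logical per frame).
#' @export
solve_inverse_kinematics <- function(model, marker_frames, weights = NULL,
                                     q0 = NULL, tol = 1e-10) {
  frames <- .as_marker_frames(model, marker_frames)
  mnames <- names(model$markers)
  if (is.null(weights))
    weights <- vapply(model$markers, `[[`, numeric(1), "weight")
  weights <- weights[mnames]
  nq <- length(coord_names(model))
  ranges <- coord_ranges(model)
  nf <- length(frames$time)
  Q <- matrix(NA_real_, nf, nq, dimnames = list(NULL, coord_names(model)))
  rmse <- rep(NA_real_, nf)
  flagged <- logical(nf)
  q_default <- default_q(model)
  q_prev <- if (is.null(q0)) q_default else check_q(model, q0)
  sq_err_sum <- 0; n_err <- 0
  for (f in seq_len(nf)) {
    target <- frames$markers[[f]][mnames, , drop = FALSE]
    vis <- stats::complete.cases(target)
    if (sum(vis) < 3) { flagged[f] <- TRUE; next }
    # the prior anchors at the previous frame's solution: along momentarily
    # unobservable directions (flat objective) the minimum then stays where
    # the last frame left it, giving temporal coherence by construction
    sol <- .ik_solve_frame(model, target, weights, q_prev, ranges, tol = tol,
                           reg = 1e-4, q_ref = q_prev)
    # rescue trapped frames: if this frame fits much worse than the recent
    # ones, retry from the model's default pose and keep the better fit
    recent <- rmse[seq_len(f - 1)]
    recent <- recent[!is.na(recent)]
    med <- if (length(recent)) stats::median(utils::tail(recent, 20)) else Inf
    rmse_f <- sqrt(mean(rowSums(
      .ik_residual(model, sol$q, target, weights)$err^2)[vis]))
    if (rmse_f > 0.008 || (is.finite(med) && rmse_f > 2 * med + 0.002)) {
      # retry from the default pose, and from the warm-start solution
      # reflected about the defaults: a ball joint has a mirrored branch
      # (plane +/- 180 deg with elevation negated) that fits identically
      # while the limb hangs but runs into the coordinate clamps once it
      # elevates; the reflection maps that branch back onto the true one
      cands <- list(q_default,
                    pmin(pmax(2 * q_default - sol$q, ranges[, 1]),
                         ranges[, 2]))
      for (qc in cands) {
        alt <- .ik_solve_frame(model, target, weights, qc, ranges,
                               tol = tol, q_ref = q_default)
        # decisive improvement only: in degenerate poses (arm hanging) the
        # mirror branch fits equally well up to noise, and hopping between
        # equal-fit branches would break temporal continuity
        if (alt$f < 0.5 * sol$f) sol <- alt
      }
    }
    # polish with the prior re-anchored at the current solution: this
    # removes the default-pose bias on well-observed coordinates while
    # still pinning momentarily unobservable directions (a reg = 0 polish
    # would chase per-frame noise along the sloppy gh_plane/gh_rot pair
    # with the arm hanging, producing large frame-to-frame swings)
    sol <- .ik_solve_frame(model, target, weights, sol$q, ranges, tol = tol,
                           max_iter = 15, reg = 1e-5, q_ref = sol$q)
    Q[f, ] <- sol$q
    q_prev <- sol$q
    err <- .ik_residual(model, sol$q, target, weights)$err
    d2 <- rowSums(err^2)[vis]
    rmse[f] <- sqrt(mean(d2))
    sq_err_sum <- sq_err_sum + sum(d2); n_err <- n_err + length(d2)
  }
  # interpolate flagged frames
  if (any(flagged) && any(!flagged)) {
    solved <- which(!flagged)
    for (j in seq_len(nq))
      Q[flagged, j] <- stats::approx(frames$time[solved], Q[solved, j],
                                     frames$time[flagged], rule = 2)$y
  }
  structure(list(time = frames$time, q = Q, rmse = rmse,
                 rmse_total = sqrt(sq_err_sum / max(1, n_err)),
                 flagged = flagged),
            class = "ik_result")
}

#' @keywords internal
.as_marker_frames <- function(model, marker_frames) {
  if (inherits(marker_frames, "trc_data")) {
    mnames <- marker_frames$marker_names
    nf <- length(marker_frames$time)
    lst <- vector("list", nf)
    for (f in seq_len(nf)) {
      m <- marker_frames$positions[f, , , drop = TRUE]
      m <- matrix(m, ncol = 3, dimnames = list(mnames, c("x", "y", "z")))
      lst[[f]] <- m
    }
    return(list(time = marker_frames$time, markers = lst))
  }
  if (is.list(marker_frames) && !is.null(marker_frames$markers))
    return(marker_frames)
  stop("marker_frames must be a trc_data object or a list(time, markers)")
}

#' Calibrate the scapulothoracic ellipsoid from a marker trial
#'
#' Optimizes the ellipsoid radii and tilt (three small rotations applied to
#' the joint frame) to minimize the total inverse-kinematics marker error on
#' a calibration trial. The returned objective value never exceeds the
#' pre-fit value (best-seen parameters are kept).
#'
#' @param model a [shoulder_model()] whose scapulothoracic joint is named
#'   `"scapulothoracic"`.
#' @param marker_frames calibration trial (see [solve_inverse_kinematics()]).
#' @param frame_stride use every `frame_stride`-th frame in the objective
#'   (IK inside an optimizer loop is the dominant cost).
#' @param maxit Nelder-Mead iteration budget.
#' @return list with `model` (updated), `radii`, `tilt` (rad, rotations
#'   about the joint-frame x, y, z), `objective_before`, `objective_after`.
#' @export
fit_thorax_ellipsoid <- function(model, marker_frames, frame_stride = 1,
                                 maxit = 300) {
  frames <- .as_marker_frames(model, marker_frames)
  sel <- seq(1, length(frames$time), by = frame_stride)
  sub <- list(time = frames$time[sel], markers = frames$markers[sel])
  ji <- which(vapply(model$joints, `[[`, character(1), "name") == "scapulothoracic")
  if (!length(ji)) stop("model has no 'scapulothoracic' joint")
  base_offset <- model$joints[[ji]]$parent_offset
  base_radii <- model$joints[[ji]]$params$radii
  nm <- length(model$markers)
  if (nm < 4) stop("degenerate marker set: ellipsoid fit needs >= 4 markers")

  apply_par <- function(par) {
    radii <- base_radii * exp(par[1:3])
    tilt <- par[4:6]
    Rt <- rot_x(tilt[1]) %*% rot_y(tilt[2]) %*% rot_z(tilt[3])
    m <- model
    m$joints[[ji]]$params$radii <- radii
    m$joints[[ji]]$parent_offset <- base_offset %*% make_transform(Rt)
    m
  }
  objective <- function(par) {
    m <- apply_par(par)
    ik <- solve_inverse_kinematics(m, sub)
    ik$rmse_total^2 * 1e6 # mm^2 scale keeps Nelder-Mead steps reasonable
  }
  f0 <- objective(rep(0, 6))
  opt <- stats::optim(rep(0, 6), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  best_par <- if (opt$value <= f0) opt$par else rep(0, 6)
  best_val <- min(opt$value, f0)
  m <- apply_par(best_par)
  list(model = m, radii = m$joints[[ji]]$params$radii,
       tilt = best_par[4:6],
       objective_before = f0, objective_after = best_val)
}
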