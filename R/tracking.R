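# Muscle-driven tracking: PD acceleration tracking plus per-control-step
# static redundancy resolution over activations with reserve actuators, and
# forward integration of the muscle-driven skeleton.
#
# The controller is a per-step static-optimization variant of computed
# muscle control: at each control step (default 10 ms) it linearizes muscle
# force in activation at the current kinematics, solves a box-constrained
# quadratic program for activations (reserve torques eliminated
# analytically), and applies first-order activation dynamics as a rate
# limit on the commanded activations while integrating the skeleton at a
# fixed fine step (default 1 ms) with the muscle geometry frozen over the
# control step.

#' PD desired accelerations for trajectory tracking
#'
#' `qdd* = qdd_des + k_v (qd_des - qd) + k_p (q_des - q)`; the defaults are
#' critically damped (`k_v = 2 sqrt(k_p)`).
#'
#' @param q_des,qd_des,qdd_des desired position, velocity, acceleration.
#' @param q,qd current position and velocity.
#' @param k_p proportional gain (1/s^2).
#' @param k_v derivative gain (1/s).
#' @return desired acceleration vector.
#' @export
desired_accelerations <- function(q_des, qd_des, qdd_des, q, qd,
                                  k_p = 100, k_v = 2 * sqrt(k_p)) {
  qdd_des + k_v * (qd_des - qd) + k_p * (q_des - q)
}

#' Resolve muscle redundancy at one instant
#'
#' Solves `min sum(a^2) + w_r sum((r / r_scale)^2)` subject to the
#' linearized equations of motion
#' `M qdd* + c = R (a * F_act + F_pas) + g + r`, `0 <= a <= 1`, where `R`
#' is the moment-arm matrix and the reserve torques `r` (one per
#' coordinate) are eliminated analytically: `r = b - A a`. The resulting
#' box-constrained strictly convex quadratic is solved with projected
#' quasi-Newton iterations (`optim` L-BFGS-B) with an analytic gradient,
#' warm-started.
#'
#' @param A n_q x n_m matrix of generalized force per unit activation
#'   (`R diag(F_act)`).
#' @param b length n_q net generalized force the actuators must supply
#'   (`M qdd* + c - g - R F_pas`).
#' @param w_r reserve penalty weight.
#' @param r_scale reserve scale (N m).
#' @param a0 warm-start activations.
#' @return list with `a` (activations), `reserves` (`b - A a`), and
#'   `objective`.
#' @export
resolve_redundancy <- function(A, b, w_r = 1000, r_scale = 1, a0 = NULL) {
  nm <- ncol(A)
  if (is.null(a0)) a0 <- rep(0.05, nm)
  a0 <- pmin(1, pmax(0, a0))
  wr <- w_r / r_scale^2
  fn <- function(a) {
    r <- b - A %*% a
    sum(a^2) + wr * sum(r^2)
  }
  gr <- function(a) {
    r <- b - A %*% a
    2 * a - 2 * wr * drop(crossprod(A, r))
  }
  opt <- stats::optim(a0, fn, gr, method = "L-BFGS-B", lower = 0, upper = 1,
                      control = list(maxit = 200, factr = 1e4))
  a <- opt$par
  list(a = a, reserves = drop(b - A %*% a), objective = opt$value)
}

#' @keywords internal
.traj_splines <- function(time, qmat) {
  lapply(seq_len(ncol(qmat)), function(j)
    stats::splinefun(time, qmat[, j], method = "natural"))
}

#' Muscle-driven tracking simulation
#'
#' Tracks a coordinate trajectory with muscle forces plus penalized reserve
#' actuators, integrating the skeleton at a fixed fine step. See the module
#' description above for the control scheme.
#'
#' @param model a [shoulder_model()].
#' @param q_traj data.frame or matrix whose first column is time (s) and
#'   remaining columns are coordinates in model order (rad), or an
#'   `ik_result`.
#' @param dt integration step (s).
#' @param dt_control control (redundancy-resolution) step (s).
#' @param k_p,k_v tracking gains.
#' @param w_r,r_scale reserve penalty weight and scale.
#' @param t_end simulate up to this time (default: end of trajectory).
#' @param a_init initial activations.
#' @param armature small constant inertia (kg m^2) added to the mass-matrix
#'   diagonal; regularizes poses where a coordinate is momentarily inertialess
#'   (e.g. the humeral elevation plane with the arm hanging).
#' @return object of class `simulation_result`: list with `time` (control
#'   grid), `q`, `qd` (matrices), `a`, `F_mtu`, `l_mtu`, `v_mtu`
#'   (n_time x n_muscles), `reserves` (n_time x n_q), `energy` (list with
#'   muscle work, reserve work, KE and PE trajectories) and `q_des`.
#' @export
run_tracking <- function(model, q_traj, dt = 0.001, dt_control = 0.01,
                         k_p = 100, k_v = 2 * sqrt(k_p),
                         w_r = 1000, r_scale = 1, t_end = NULL,
                         a_init = 0.02, armature = 1e-4) {
  if (inherits(q_traj, "ik_result"))
    q_traj <- data.frame(time = q_traj$time, q_traj$q)
  q_traj <- as.matrix(q_traj)
  tvec <- q_traj[, 1]
  qmat <- q_traj[, -1, drop = FALSE]
  cn <- coord_names(model)
  if (ncol(qmat) != length(cn))
    stop("q_traj must provide all model coordinates")
  if (is.null(t_end)) t_end <- max(tvec)
  spl <- .traj_splines(tvec, qmat)
  des <- function(t, deriv = 0) vapply(spl, function(s) s(t, deriv), numeric(1))

  nq <- length(cn); nm <- length(model$muscles)
  mn <- names(model$muscles)
  n_ctrl <- max(1L, round((t_end - tvec[1]) / dt_control))
  n_sub <- max(1L, round(dt_control / dt))
  dt <- dt_control / n_sub

  q <- des(tvec[1]); qd <- des(tvec[1], 1)
  a <- rep(a_init, nm)
  params <- lapply(model$muscles, `[[`, "params")
  deps <- muscle_coord_dependencies(model)
  wcache <- new.env(parent = emptyenv())

  times <- numeric(n_ctrl + 1)
  Q <- matrix(NA_real_, n_ctrl + 1, nq, dimnames = list(NULL, cn))
  QD <- Q
  Qdes <- Q
  Amat <- matrix(NA_real_, n_ctrl + 1, nm, dimnames = list(NULL, mn))
  Fmat <- Amat; Lmat <- Amat; Vmat <- Amat; Abar_mat <- Amat
  Rres <- matrix(NA_real_, n_ctrl + 1, nq, dimnames = list(NULL, cn))
  KE <- numeric(n_ctrl + 1); PE <- numeric(n_ctrl + 1)
  muscle_work <- 0; reserve_work <- 0
  pos_work <- rep(0, nm)
  mus_work_each <- rep(0, nm)

  a_cmd <- a
  a_bar <- a
  for (step in 0:n_ctrl) {
    t_now <- tvec[1] + step * dt_control
    # geometry and dynamics at the control-step head
    Rarm <- moment_arm_matrix(model, q, deps = deps, cache = wcache)
    L <- muscle_lengths(model, q, cache = wcache)
    v <- -drop(crossprod(Rarm, qd))
    M <- mass_matrix(model, q) + diag(armature, nq)
    gvec <- gravity_forces(model, q)
    cvec <- coriolis_forces(model, q, qd)

    comp <- lapply(seq_len(nm), function(i)
      tendon_force_components(params[[i]], L[i], v[i]))
    F_act <- vapply(comp, `[[`, numeric(1), "f_active")
    F_pas <- vapply(comp, `[[`, numeric(1), "f_passive")

    # record state at this control node
    idx <- step + 1
    times[idx] <- t_now
    Q[idx, ] <- q; QD[idx, ] <- qd; Qdes[idx, ] <- des(min(t_now, t_end))
    Lmat[idx, ] <- L; Vmat[idx, ] <- v
    F_now <- a * F_act + F_pas
    Amat[idx, ] <- a; Fmat[idx, ] <- F_now
    KE[idx] <- 0.5 * drop(t(qd) %*% M %*% qd)
    PE[idx] <- potential_energy(model, q)

    if (step == n_ctrl) { Rres[idx, ] <- 0; break }

    td <- min(t_now + dt_control / 2, t_end) # demand at the step midpoint
    qdd_star <- desired_accelerations(des(td), des(td, 1), des(td, 2),
                                      q, qd, k_p, k_v)
    b <- drop(M %*% qdd_star) + cvec - gvec - drop(Rarm %*% F_pas)
    A_lin <- Rarm * rep(F_act, each = nq)
    # the QP chooses the target activation for this control step
    sol <- resolve_redundancy(A_lin, b, w_r, r_scale, a0 = a_bar)
    a_bar <- sol$a
    Abar_mat[idx, ] <- a_bar
    if (step == 0) {
      # start from the static-equilibrium activations so the initial
      # activation ramp does not show up as a reserve transient
      a <- a_bar
      Amat[idx, ] <- a
      Fmat[idx, ] <- a * F_act + F_pas
    }
    # deadbeat inversion of the first-order activation lag: command the
    # excitation that lands the activation on the target at the step end
    e_lag <- ifelse(a_bar > a, exp(-dt_control / 0.010), exp(-dt_control / 0.040))
    a_cmd <- pmin(1, pmax(0, (a_bar - e_lag * a) / (1 - e_lag)))

    # integrate the substeps with geometry, mass and moment arms frozen;
    # gravity and the PD law are refreshed each substep and the reserve
    # torque is the exact residual that enforces the commanded
    # acceleration (logged, penalized at the QP stage, never free)
    res_acc <- rep(0, nq)
    for (k in seq_len(n_sub)) {
      a <- activation_dynamics(a, a_cmd, dt)
      Fm <- a * F_act + F_pas
      tau <- drop(Rarm %*% Fm)
      gsub <- gravity_forces(model, q)
      tk <- min(t_now + k * dt, t_end)
      qdd <- desired_accelerations(des(tk), des(tk, 1), des(tk, 2),
                                   q, qd, k_p, k_v)
      res <- drop(M %*% qdd) + cvec - tau - gsub
      res_acc <- res_acc + res / n_sub
      v_m <- -drop(crossprod(Rarm, qd))
      p_mus <- Fm * (-v_m)
      qd_new <- qd + qdd * dt
      q_new <- q + qd_new * dt
      v_m_new <- -drop(crossprod(Rarm, qd_new))
      p_mus_new <- Fm * (-v_m_new)
      muscle_work <- muscle_work + sum(p_mus + p_mus_new) / 2 * dt
      mus_work_each <- mus_work_each + (p_mus + p_mus_new) / 2 * dt
      reserve_work <- reserve_work +
        sum(res * (qd + qd_new) / 2) * dt
      qd <- qd_new; q <- q_new
    }
    Rres[idx, ] <- res_acc
  }
  structure(list(time = times, q = Q, qd = QD, q_des = Qdes, a = Amat,
                 a_target = Abar_mat,
                 F_mtu = Fmat, l_mtu = Lmat, v_mtu = Vmat, reserves = Rres,
                 energy = list(KE = KE, PE = PE, muscle_work = muscle_work,
                               muscle_work_each = mus_work_each,
                               reserve_work = reserve_work),
                 dt_control = dt_control, model_name = model$name),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %d control steps over %.3f s, %d muscles>\n",
              length(x$time) - 1, diff(range(x$time)), ncol(x$a)))
  err <- sqrt(colMeans((x$q - x$q_des)^2, na.rm = TRUE))
  cat(sprintf("  coordinate tracking RMS error: max %.4f rad\n", max(err)))
  invisible(x)
}

#' RMS reserve share per coordinate of a tracking simulation
#'
#' Ratio of RMS reserve generalized force to RMS muscle-generated
#' generalized force for each coordinate; reserve actuators are a crutch,
#' not an actor, so on well-posed tasks this should be small.
#'
#' @param model the model used for the simulation.
#' @param result a `simulation_result`.
#' @return named numeric vector of per-coordinate reserve shares.
#' @export
reserve_share <- function(model, result) {
  nt <- nrow(result$q)
  nq <- ncol(result$q)
  tau_m <- matrix(0, nt, nq)
  deps <- muscle_coord_dependencies(model)
  wcache <- new.env(parent = emptyenv())
  for (i in seq_len(nt)) {
    Rarm <- moment_arm_matrix(model, result$q[i, ], deps = deps, cache = wcache)
    tau_m[i, ] <- drop(Rarm %*% result$F_mtu[i, ])
  }
  rms <- function(x) sqrt(mean(x^2))
  share <- vapply(seq_len(nq), function(j)
    rms(result$reserves[, j][!is.na(result$reserves[, j])]) /
      max(rms(tau_m[, j]), 1e-9), numeric(1))
  stats::setNames(share, colnames(result$q))
}
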