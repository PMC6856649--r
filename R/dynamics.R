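# Multibody dynamics of the coordinate tree, assembled from body Jacobians
# obtained by central differences of the forward kinematics. With only 8
# coordinates and slow upper-extremity motions this is accurate and keeps
# the dynamics derivation transparent:
#   M(q)      = sum_b  m_b Jv_b' Jv_b + Jw_b' (R I_b R') Jw_b
#   g(q)      = -dPE/dq                       (central difference)
#   c(q, qd)  = (dM/dq quadratic form)        Christoffel contraction
# The hand-held mass contributes as a point mass on the forearm segment.

#' @keywords internal
.moving_bodies <- function(model) {
  # bodies whose frame depends on q (skip those welded to ground transitively)
  welded <- "ground"
  for (j in model$joints)
    if (j$type == "weld" && j$parent %in% welded) welded <- c(welded, j$child)
  setdiff(names(model$bodies), welded)
}

#' @keywords internal
.body_jacobians <- function(model, q, h = 1e-6) {
  q <- check_q(model, q)
  nq <- length(q)
  mb <- .moving_bodies(model)
  f0 <- forward_kinematics(model, q)
  out <- list()
  for (b in mb) out[[b]] <- list(Jv = matrix(0, 3, nq), Jw = matrix(0, 3, nq),
                                 R = f0[[b]][1:3, 1:3],
                                 p_com = transform_point(f0[[b]], model$bodies[[b]]$com))
  Jh <- if (model$hand_mass > 0) matrix(0, 3, nq) else NULL
  for (i in seq_len(nq)) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    fp <- forward_kinematics(model, qp)
    fm <- forward_kinematics(model, qm)
    for (b in mb) {
      com <- model$bodies[[b]]$com
      out[[b]]$Jv[, i] <- (transform_point(fp[[b]], com) -
                             transform_point(fm[[b]], com)) / (2 * h)
      dR <- (fp[[b]][1:3, 1:3] - fm[[b]][1:3, 1:3]) / (2 * h)
      out[[b]]$Jw[, i] <- vee3(dR %*% t(f0[[b]][1:3, 1:3]))
    }
    if (!is.null(Jh)) {
      hp <- model$hand_point
      Jh[, i] <- (transform_point(fp[[hp$body]], hp$loc) -
                    transform_point(fm[[hp$body]], hp$loc)) / (2 * h)
    }
  }
  list(bodies = out, Jh = Jh)
}

#' Joint-space mass matrix
#'
#' @param model a [shoulder_model()].
#' @param q generalized coordinates.
#' @return n_q x n_q symmetric positive-definite mass matrix.
#' @export
mass_matrix <- function(model, q) {
  jac <- .body_jacobians(model, q)
  nq <- length(coord_names(model))
  M <- matrix(0, nq, nq)
  for (b in names(jac$bodies)) {
    bj <- jac$bodies[[b]]
    seg <- model$bodies[[b]]
    Iw <- bj$R %*% seg$inertia %*% t(bj$R)
    M <- M + seg$mass * crossprod(bj$Jv) + t(bj$Jw) %*% Iw %*% bj$Jw
  }
  if (!is.null(jac$Jh)) M <- M + model$hand_mass * crossprod(jac$Jh)
  (M + t(M)) / 2
}

#' Gravitational potential energy of the model at a pose
#'
#' Sum over segments (and the hand-held mass) of `-m g . p_com`.
#'
#' @inheritParams mass_matrix
#' @param frames optional precomputed [forward_kinematics()] output.
#' @return Potential energy in joules (gravity vector taken from the model).
#' @export
potential_energy <- function(model, q, frames = NULL) {
  if (is.null(frames)) frames <- forward_kinematics(model, q)
  gvec <- model$gravity
  pe <- 0
  for (b in .moving_bodies(model)) {
    seg <- model$bodies[[b]]
    pe <- pe - seg$mass * sum(gvec * transform_point(frames[[b]], seg$com))
  }
  if (model$hand_mass > 0)
    pe <- pe - model$hand_mass *
      sum(gvec * transform_point(frames[[model$hand_point$body]],
                                 model$hand_point$loc))
  pe
}

#' Generalized gravity force
#'
#' `g(q) = -dPE/dq` by central differences; appears on the right-hand side
#' of the equations of motion `M qdd + c = tau + g`.
#'
#' @inheritParams mass_matrix
#' @param h finite-difference step.
#' @return length n_q numeric vector.
#' @export
gravity_forces <- function(model, q, h = 1e-6) {
  q <- check_q(model, q)
  nq <- length(q)
  g <- numeric(nq)
  for (i in seq_len(nq)) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    g[i] <- -(potential_energy(model, qp) - potential_energy(model, qm)) / (2 * h)
  }
  g
}

#' Velocity-dependent (Coriolis/centrifugal) generalized forces
#'
#' Christoffel contraction of the mass-matrix gradient:
#' `c_k = sum_ij (dM_kj/dq_i - 0.5 dM_ij/dq_k) qd_i qd_j`, with `dM/dq`
#' by central differences. Satisfies the power identity
#' `qd . c = 0.5 qd' Mdot qd` used by the work-energy bookkeeping.
#'
#' @inheritParams mass_matrix
#' @param qd generalized velocities.
#' @param h finite-difference step for `dM/dq`.
#' @return length n_q numeric vector.
#' @export
coriolis_forces <- function(model, q, qd, h = 1e-5) {
  q <- check_q(model, q)
  nq <- length(q)
  if (all(abs(qd) < 1e-14)) return(numeric(nq))
  dM <- array(0, c(nq, nq, nq))
  for (i in seq_len(nq)) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    dM[, , i] <- (mass_matrix(model, qp) - mass_matrix(model, qm)) / (2 * h)
  }
  cc <- numeric(nq)
  for (k in seq_len(nq)) {
    s <- 0
    for (i in seq_len(nq))
      s <- s + sum((dM[k, , i] - 0.5 * dM[i, , k]) * qd) * qd[i]
    cc[k] <- s
  }
  cc
}

#' Kinetic energy at a state
#'
#' @inheritParams coriolis_forces
#' @return `0.5 qd' M(q) qd` in joules.
#' @export
kinetic_energy <- function(model, q, qd) {
  0.5 * drop(t(qd) %*% mass_matrix(model, q) %*% qd)
}
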