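# Rigid-tendon Hill-type musculotendon mechanics and first-order activation
# dynamics.
#
# Curve shapes (all configurable through `hill_curves()`):
#  * active force-length: Gaussian exp(-(l~ - 1)^2 / 0.45), shifted and
#    rescaled so it is exactly 0 at l~ = 0 and exactly 1 at l~ = 1; the
#    shift keeps tendon force continuous across the slack transition.
#  * passive force-length: exponential engaging above optimal length,
#    f_P = (exp(k (l~ - 1) / e0) - 1) / (exp(k) - 1), k = 4, e0 = 1.0
#    (reaches F_max at 100% fiber strain; these actuators aggregate several
#    anatomical bundles whose staggered passive engagement softens the
#    lumped curve).
#  * force-velocity: Hill hyperbola on the shortening side (a_f = 0.25),
#    C1-continuous eccentric branch with plateau 1.4.
# Maximum shortening velocity v_max = 10 l_opt / s; pennation constant.

#' Hill-curve constants
#'
#' @param fl_gamma width of the active force-length Gaussian.
#' @param pe_k,pe_e0 passive-curve exponent and strain at which the passive
#'   curve reaches F_max.
#' @param af force-velocity shape factor (shortening side).
#' @param flen eccentric force plateau (multiple of isometric force).
#' @param vmax_scale maximum shortening velocity in optimal fiber lengths
#'   per second.
#' @return list of curve constants, accepted by the `curves` argument of
#'   [tendon_force()].
#' @export
hill_curves <- function(fl_gamma = 0.45, pe_k = 4, pe_e0 = 1.0,
                        af = 0.25, flen = 1.4, vmax_scale = 10) {
  list(fl_gamma = fl_gamma, pe_k = pe_k, pe_e0 = pe_e0, af = af,
       flen = flen, vmax_scale = vmax_scale)
}

#' @keywords internal
force_length_active <- function(lnorm, curves = hill_curves()) {
  g <- curves$fl_gamma
  base <- exp(-1 / g)
  pmax(0, (exp(-(lnorm - 1)^2 / g) - base) / (1 - base))
}

#' @keywords internal
force_length_passive <- function(lnorm, curves = hill_curves()) {
  k <- curves$pe_k; e0 <- curves$pe_e0
  ifelse(lnorm > 1, (exp(k * (lnorm - 1) / e0) - 1) / (exp(k) - 1), 0)
}

#' @keywords internal
force_velocity <- function(vnorm, curves = hill_curves()) {
  af <- curves$af; flen <- curves$flen
  # vnorm = v_fiber / v_max, positive when lengthening
  slope0 <- 1 + 1 / af # concentric-branch slope at vnorm = 0
  ifelse(vnorm < 0,
         pmax(0, (1 + vnorm) / (1 - vnorm / af)),
         flen - (flen - 1) / (1 + vnorm * slope0 / (flen - 1)))
}

#' Rigid-tendon fiber kinematics
#'
#' Under the rigid-tendon assumption the fiber length follows directly from
#' the musculotendon length: `l_fiber = (l_mtu - l_ts) / cos(pennation)`,
#' and the fiber velocity scales the same way. If `l_mtu <= l_ts` the unit
#' is slack: fiber length 0, zero force, flagged.
#'
#' @param params a [muscle_parameters()].
#' @param l_mtu musculotendon length (m).
#' @param v_mtu musculotendon lengthening velocity (m/s; positive =
#'   lengthening).
#' @return list with `l_fiber`, `v_fiber` (m, m/s) and logical `slack`.
#' @export
fiber_kinematics <- function(params, l_mtu, v_mtu = 0) {
  cp <- cos(params$pennation * pi / 180)
  if (l_mtu <= params$l_ts)
    return(list(l_fiber = 0, v_fiber = 0, slack = TRUE))
  list(l_fiber = (l_mtu - params$l_ts) / cp, v_fiber = v_mtu / cp,
       slack = FALSE)
}

#' Hill-type tendon force
#'
#' `F = (a f_L(l~) f_V(v~) + f_P(l~)) F_max cos(pennation)` with
#' `l~ = l_fiber / l_opt` and `v~ = v_fiber / (vmax_scale * l_opt)`.
#' Slack units produce zero force; F is always nonnegative and continuous in
#' `l_mtu` across the slack transition.
#'
#' @inheritParams fiber_kinematics
#' @param a activation in [0, 1].
#' @param curves curve constants from [hill_curves()].
#' @return Force in newtons.
#' @export
tendon_force <- function(params, l_mtu, v_mtu = 0, a = 0,
                         curves = hill_curves()) {
  fk <- fiber_kinematics(params, l_mtu, v_mtu)
  if (fk$slack) return(0)
  lnorm <- fk$l_fiber / params$l_opt
  vnorm <- fk$v_fiber / (curves$vmax_scale * params$l_opt)
  cp <- cos(params$pennation * pi / 180)
  f <- (a * force_length_active(lnorm, curves) * force_velocity(vnorm, curves) +
          force_length_passive(lnorm, curves)) * params$f_max * cp
  max(0, f)
}

#' Active and passive force components at given kinematics
#'
#' Splits [tendon_force()] into the part proportional to activation
#' (`f_active`, the force at a = 1 minus the passive part) and the passive
#' part, which the tracking controller uses to pose its linear redundancy
#' problem.
#'
#' @inheritParams tendon_force
#' @return list with `f_active`, `f_passive` (N).
#' @export
tendon_force_components <- function(params, l_mtu, v_mtu = 0,
                                    curves = hill_curves()) {
  fk <- fiber_kinematics(params, l_mtu, v_mtu)
  if (fk$slack) return(list(f_active = 0, f_passive = 0))
  lnorm <- fk$l_fiber / params$l_opt
  vnorm <- fk$v_fiber / (curves$vmax_scale * params$l_opt)
  cp <- cos(params$pennation * pi / 180)
  list(f_active = force_length_active(lnorm, curves) *
         force_velocity(vnorm, curves) * params$f_max * cp,
       f_passive = force_length_passive(lnorm, curves) * params$f_max * cp)
}

#' First-order activation dynamics
#'
#' Exact exponential update of the first-order lag of activation `a` toward
#' excitation `u`, with activation time constant 10 ms (`u > a`) and
#' deactivation time constant 40 ms (`u <= a`). Output clamped to [0, 1].
#'
#' @param a current activation in [0, 1] (vectorized).
#' @param u excitation in [0, 1].
#' @param dt time step (s), > 0.
#' @param tau_act,tau_deact time constants (s).
#' @return activation after `dt`.
#' @export
activation_dynamics <- function(a, u, dt, tau_act = 0.010, tau_deact = 0.040) {
  stopifnot(dt > 0)
  tau <- ifelse(u > a, tau_act, tau_deact)
  pmin(1, pmax(0, u + (a - u) * exp(-dt / tau)))
}
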