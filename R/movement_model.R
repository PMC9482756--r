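#' Resistance parameters of the waxy medium
#'
#' The softened wax of the typodont resists tooth movement with a drag term
#' \eqn{f_D = \tfrac12 C_D \rho(t) A v^2} and an inertia (added-mass) term
#' \eqn{f_L = C_M M_0 \,\mathrm{d}v/\mathrm{d}t}. The wax density may decay
#' with immersion time; the published model cites an external expression for
#' \eqn{\rho(t)} without reproducing it, so the default here is a constant
#' density, with an optional one-parameter exponential decay
#' \eqn{\rho(t) = \rho_\infty + (\rho_0 - \rho_\infty) e^{-t/\tau}} as a
#' clearly non-reference stand-in.
#'
#' Defaults are nominal order-of-magnitude values (paraffin-type wax,
#' premolar-scale areas); the reference study does not print its constants,
#' and only a composite compliance is identifiable from displacement data
#' (see the calibration functions).
#'
#' @param C_D Drag coefficient, dimensionless (>= 0).
#' @param C_M Added-mass (inertia) coefficient, dimensionless (>= 0).
#' @param A Reference area, m^2 (>= 0).
#' @param M0_mass Displaced/reference mass for the inertia term, kg (>= 0).
#'   (Named to avoid collision with the bending moment M0.)
#' @param rho0 Wax density at t = 0, kg/m^3 (> 0).
#' @param rho_inf Long-time density, kg/m^3; defaults to `rho0` (constant).
#' @param tau Density decay time constant, s; `Inf` means constant density.
#' @return An object of class `tloop_resistance`.
#' @export
resistance_params <- function(C_D = 0.5, C_M = 1, A = 6e-5, M0_mass = 1e-3,
                              rho0 = 900, rho_inf = rho0, tau = Inf) {
  vals <- c(C_D = C_D, C_M = C_M, A = A, M0_mass = M0_mass)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    rlang::abort("C_D, C_M, A and M0_mass must be finite and non-negative.",
                 class = "tloop_input_error")
  }
  if (rho0 <= 0 || rho_inf <= 0 || tau <= 0) {
    rlang::abort("Densities and tau must be positive.",
                 class = "tloop_input_error")
  }
  structure(list(C_D = C_D, C_M = C_M, A = A, M0_mass = M0_mass,
                 rho0 = rho0, rho_inf = rho_inf, tau = tau),
            class = "tloop_resistance")
}

#' Wax density at time t
#'
#' @param res A [resistance_params()] object.
#' @param t Time(s), s.
#' @return Density in kg/m^3.
#' @export
rho_at <- function(res, t) {
  stopifnot(inherits(res, "tloop_resistance"))
  if (is.infinite(res$tau)) {
    rep(res$rho0, length(t))
  } else {
    res$rho_inf + (res$rho0 - res$rho_inf) * exp(-t / res$tau)
  }
}

#' Kinematic parameters of the moving tooth
#'
#' @param v0 Initial velocity, m/s (>= 0). Teeth start at rest by default.
#' @param t1 Duration of movement, s (> 0). Default 120 s, the immersion
#'   time of the water-bath measurement the model describes.
#' @param m0 Tooth mass, kg (> 0). Default 2 g, a premolar-scale mass.
#' @return An object of class `tloop_kinematics`.
#' @export
kinematic_params <- function(v0 = 0, t1 = 120, m0 = 2e-3) {
  if (!is.finite(v0) || v0 < 0 || !is.finite(t1) || t1 <= 0 ||
      !is.finite(m0) || m0 <= 0) {
    rlang::abort("Require v0 >= 0, t1 > 0, m0 > 0.",
                 class = "tloop_input_error")
  }
  structure(list(v0 = v0, t1 = t1, m0 = m0), class = "tloop_kinematics")
}

#' Dynamic resistance of the waxy medium
#'
#' Decomposes the total resistance into drag and inertia:
#' \eqn{f_D = \tfrac12 C_D \rho(t) A v^2},
#' \eqn{f_L = C_M M_0\, \mathrm{d}v/\mathrm{d}t}, \eqn{f = f_D + f_L}.
#'
#' @param res A [resistance_params()] object.
#' @param v Velocity, m/s. Vectorised.
#' @param dvdt Acceleration, m/s^2. Vectorised.
#' @param t Time, s (enters through the density model). Default 0.
#' @return A tibble with columns `f_D`, `f_L`, `f` (N), satisfying
#'   `f == f_D + f_L` exactly.
#' @export
total_resistance <- function(res, v, dvdt, t = 0) {
  stopifnot(inherits(res, "tloop_resistance"))
  f_D <- 0.5 * res$C_D * rho_at(res, t) * res$A * v^2
  f_L <- res$C_M * res$M0_mass * dvdt
  tibble::tibble(f_D = f_D, f_L = f_L, f = f_D + f_L)
}

#' Predict tooth displacement under a constant orthodontic force
#'
#' The closed-form, constant-acceleration displacement
#' \deqn{S_m = v_0 t_1 + \frac{F_0 - f_D - f_L}{2 m_0} t_1^2,}
#' with the drag frozen at the initial velocity \eqn{v_0}. The inertia term
#' contains the acceleration itself; by default it is resolved by the exact
#' linear solve \eqn{a_0 = (F_0 - f_D) / (m_0 + C_M M_0)}, and the form
#' above is evaluated with \eqn{f_L = C_M M_0 a_0}. Supplying `dvdt`
#' evaluates the formula literally with that constant. With zero resistance
#' the model reduces to \eqn{v_0 t_1 + F_0 t_1^2/(2 m_0)}.
#'
#' @param F0 Orthodontic force(s), N. Vectorised.
#' @param res A [resistance_params()] object.
#' @param kin A [kinematic_params()] object.
#' @param dvdt Optional constant acceleration for the inertia term, m/s^2;
#'   `NULL` (default) uses the self-consistent solve.
#' @param t Time at which the density is evaluated, s.
#' @return A tibble with columns `F0_N`, `f_D_N`, `f_L_N`, `f_N`, `F_net_N`,
#'   `a0_ms2`, `S_m` (displacement, m).
#' @export
predict_displacement <- function(F0, res = resistance_params(),
                                 kin = kinematic_params(), dvdt = NULL,
                                 t = 0) {
  stopifnot(inherits(res, "tloop_resistance"),
            inherits(kin, "tloop_kinematics"))
  if (any(!is.finite(F0))) {
    rlang::abort("`F0` must be finite.", class = "tloop_input_error")
  }
  f_D <- 0.5 * res$C_D * rho_at(res, t) * res$A * kin$v0^2
  if (is.null(dvdt)) {
    a0 <- (F0 - f_D) / (kin$m0 + res$C_M * res$M0_mass)
  } else {
    a0 <- (F0 - f_D - res$C_M * res$M0_mass * dvdt) / kin$m0
  }
  f_L <- if (is.null(dvdt)) res$C_M * res$M0_mass * a0 else
    res$C_M * res$M0_mass * dvdt
  F_net <- F0 - f_D - f_L
  tibble::tibble(
    F0_N = F0, f_D_N = f_D, f_L_N = f_L,
    f_N = f_D + f_L, F_net_N = F_net, a0_ms2 = a0,
    S_m = kin$v0 * kin$t1 + a0 * kin$t1^2 / 2
  )
}

#' Integrate the tooth trajectory through the waxy medium
#'
#' Explicit first-order time stepping of
#' \eqn{(m_0 + C_M M_0)\,\mathrm{d}v/\mathrm{d}t = F_0(r, t) - \tfrac12
#' C_D \rho(t) A v |v|}, the honest dynamic counterpart of the
#' constant-acceleration closed form. The driving force may depend on the
#' current displacement, so the loop force can relax as the clearance gap
#' closes. Deterministic; no randomness enters.
#'
#' @param F0_fun Either a constant force (N) or a function `function(r, t)`
#'   returning the instantaneous force, N.
#' @param res A [resistance_params()] object.
#' @param kin A [kinematic_params()] object (supplies `v0` and the horizon
#'   `t1`).
#' @param dt Time step, s; must satisfy `dt <= t1/100`.
#' @return A tibble with columns `t` (s), `r` (m), `v` (m/s).
#' @export
integrate_trajectory <- function(F0_fun, res = resistance_params(),
                                 kin = kinematic_params(), dt = kin$t1 / 1000) {
  stopifnot(inherits(res, "tloop_resistance"),
            inherits(kin, "tloop_kinematics"))
  if (!is.finite(dt) || dt <= 0 || dt > kin$t1 / 100) {
    rlang::abort("`dt` must be positive and at most t1/100.",
                 class = "tloop_input_error")
  }
  if (is.numeric(F0_fun) && length(F0_fun) == 1L) {
    F0_const <- F0_fun
    F0_fun <- function(r, t) F0_const
  }
  n <- ceiling(kin$t1 / dt)
  t <- r <- v <- numeric(n + 1L)
  v[1L] <- kin$v0
  m_eff <- kin$m0 + res$C_M * res$M0_mass
  # drag only removes momentum, so |v| should never exceed the drag-free
  # bound |v0| + |F| t1 / m_eff by a wide margin; a large overshoot marks
  # a numerically unstable step size
  v_bound <- 100 * (abs(kin$v0) +
                      (abs(F0_fun(0, 0)) + 1e-12) * kin$t1 / m_eff)
  for (k in seq_len(n)) {
    tk <- (k - 1L) * dt
    drag <- 0.5 * res$C_D * rho_at(res, tk) * res$A * v[k] * abs(v[k])
    a <- (F0_fun(r[k], tk) - drag) / m_eff
    v[k + 1L] <- v[k] + a * dt
    r[k + 1L] <- r[k] + v[k] * dt
    t[k + 1L] <- tk + dt
    if (!is.finite(v[k + 1L]) || abs(v[k + 1L]) > v_bound) {
      rlang::abort("Velocity diverged; reduce the time step `dt`.",
                   class = "tloop_instability_error")
    }
  }
  tibble::tibble(t = t, r = r, v = v)
}
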