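#' Map clearance distance to vertical-arm deflection
#'
#' The clinician opens the loop by a clearance distance `b`; for the
#' symmetric (equal Alpha/Beta) loop analysed here both arms share the
#' opening, so the default maps `b` to a maximum vertical-arm deflection
#' m = b/2. Mode `"full"` attributes the whole clearance to one arm.
#'
#' @param b Clearance distance (any length unit; the result keeps it).
#' @param mode `"half"` (default) or `"full"`.
#' @return Deflection in the same unit as `b`.
#' @export
clearance_to_deflection <- function(b, mode = c("half", "full")) {
  mode <- match.arg(mode)
  if (any(!is.finite(b)) || any(b < 0)) {
    rlang::abort("clearance `b` must be non-negative and finite.",
                 class = "tloop_input_error")
  }
  if (mode == "half") b / 2 else b
}

#' Bending moment at the arm/arc intersection
#'
#' The moment transmitted into the curved segment by the force `P` deforming
#' the vertical arm: \eqn{M_0 = -P y}.
#'
#' @param P Force deforming the vertical arm, N.
#' @param y Vertical-arm length, m (> 0).
#' @return Moment in N m.
#' @export
intersection_moment <- function(P, y) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    rlang::abort("`y` must be positive.", class = "tloop_input_error")
  }
  -P * y
}

#' Arc horizontal-arm bending deformation
#'
#' The geometric shortening transferred to the arc's horizontal arm when the
#' vertical arm of natural length `y` deflects by `m`:
#' \eqn{s = \sqrt{m^2 + y^2} - y}. For small deflections
#' \eqn{s \approx m^2/(2y)}.
#'
#' @param m_defl Maximum vertical-arm deflection, m (>= 0).
#' @param y Vertical-arm length, m (> 0).
#' @return Deformation `s` in metres, with `0 <= s <= m`.
#' @export
arc_deformation <- function(m_defl, y) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    rlang::abort("`y` must be positive.", class = "tloop_input_error")
  }
  if (any(!is.finite(m_defl)) || any(m_defl < 0)) {
    rlang::abort("`m_defl` must be non-negative.", class = "tloop_input_error")
  }
  sqrt(m_defl^2 + y^2) - y
}

# shared geometry/wire unpacking for the closed forms
.unpack_gw <- function(geom, wire) {
  stopifnot(inherits(geom, "tloop_geometry"))
  list(R = geom$R, y = geom$y, w = geom$w, EI = wire_EI(wire))
}

#' Deflection and rotation profile of the vertical arm
#'
#' Closed-form Euler--Bernoulli profile of the vertical arm loaded by the
#' end force `P`, with the curved-segment boundary values imposed at the
#' intersection x = 0: \eqn{v(0) = -M_0 R^2/(E I_z)},
#' \eqn{\theta(0) = M_0 R/(E I_z)}, with \eqn{M_0 = -P y}. The bending
#' moment is \eqn{M(x) = P (x - y)}, so
#' \deqn{\theta(x) = \frac{P}{E I_z}\left(\frac{x^2}{2} - y x\right) + \frac{M_0 R}{E I_z},
#'       \qquad
#'       v(x) = \frac{P}{E I_z}\left(\frac{x^3}{6} - \frac{y x^2}{2}\right)
#'              + \frac{M_0 R}{E I_z} x - \frac{M_0 R^2}{E I_z}.}
#' In the degenerate limit R = 0 the tip deflection reduces to the textbook
#' end-loaded cantilever \eqn{|v(y)| = P y^3/(3 E I_z)}.
#'
#' @param x Axial positions along the arm, m, each in `[0, y]`.
#' @param P End force, N.
#' @param geom A [tloop_geometry()].
#' @param wire An archwire row from [lookup_archwire()], or any list carrying
#'   `E_Pa` and `I_z_m4`.
#' @return A tibble with columns `x`, `rotation` (rad), `deflection` (m).
#' @export
vertical_arm_profile <- function(x, P, geom, wire) {
  gw <- .unpack_gw(geom, wire)
  if (any(!is.finite(x)) || any(x < 0) || any(x > gw$y + 1e-12)) {
    rlang::abort("`x` must lie within [0, y].", class = "tloop_domain_error")
  }
  M0 <- intersection_moment(P, gw$y)
  EI <- gw$EI
  theta <- P / EI * (x^2 / 2 - gw$y * x) + M0 * gw$R / EI
  v <- P / EI * (x^3 / 6 - gw$y * x^2 / 2) + M0 * gw$R / EI * x -
    M0 * gw$R^2 / EI
  tibble::tibble(x = x, rotation = theta, deflection = v)
}

#' Curved-beam profile at the arm/arc intersection
#'
#' Solution of \eqn{u'' + u = -M_0 R^2/(E I_\omega)} on the quarter-circle
#' with the clamped conditions u = u' = 0 at \eqn{\alpha = \pi/2}:
#' \deqn{u(\alpha) = \frac{M_0 R^2}{E I_\omega}(\sin\alpha - 1), \qquad
#'       \beta(\alpha) = \frac{M_0 R \cos\alpha}{E I_\omega}.}
#' The curved segment bends in the same plane as the vertical arm, so
#' \eqn{I_\omega = I_z}.
#'
#' @param alpha Angles in `[0, pi/2]`, rad.
#' @param M0 Bending moment at the intersection, N m.
#' @param R Bend radius, m.
#' @param wire Archwire row (supplies `E_Pa`, `I_z_m4`).
#' @return A tibble with columns `alpha`, `u` (m), `corner` (rad).
#' @export
curved_beam_intersection_profile <- function(alpha, M0, R, wire) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > pi / 2 + 1e-12)) {
    rlang::abort("`alpha` must lie within [0, pi/2].",
                 class = "tloop_domain_error")
  }
  EI <- wire_EI(wire)
  tibble::tibble(
    alpha = alpha,
    u = M0 * R^2 / EI * (sin(alpha) - 1),
    corner = M0 * R * cos(alpha) / EI
  )
}

#' Deflection and rotation profile of the arc horizontal arm
#'
#' Closed-form profile of the arc portion's horizontal arm under the end
#' force `G`, clamped at its junction (l = 0): with bending moment
#' \eqn{M(l) = G (l + R - w)},
#' \deqn{\theta(l) = \frac{G}{E I_z}\left(\frac{l^2}{2} + (R - w) l\right), \qquad
#'       v(l) = \frac{G}{E I_z}\left(\frac{l^3}{6} + \frac{(R - w) l^2}{2}\right).}
#' At the free end l = w - R the deflection magnitude is
#' \eqn{|G| (w-R)^3 / (3 E I_z)}.
#'
#' @param l Positions along the horizontal arm, m, each in `[0, w - R]`.
#' @param G End force, N.
#' @inheritParams vertical_arm_profile
#' @return A tibble with columns `l`, `rotation`, `deflection`.
#' @export
arc_horizontal_profile <- function(l, G, geom, wire) {
  gw <- .unpack_gw(geom, wire)
  span <- gw$w - gw$R
  if (any(!is.finite(l)) || any(l < 0) || any(l > span + 1e-12)) {
    rlang::abort("`l` must lie within [0, w - R].", class = "tloop_domain_error")
  }
  EI <- gw$EI
  tibble::tibble(
    l = l,
    rotation = G / EI * (l^2 / 2 + (gw$R - gw$w) * l),
    deflection = G / EI * (l^3 / 6 + (gw$R - gw$w) * l^2 / 2)
  )
}

#' Curved-beam profile of the lateral arc of the T
#'
#' The lateral arc is treated as a curved beam spanning `pi/4` rad, clamped
#' at its junction with the horizontal arm (\eqn{u(0) = 0},
#' \eqn{\varepsilon(0) = 0}):
#' \deqn{u(\beta) = \frac{M_0 R^2}{E I_\omega}(\cos\beta - 1), \qquad
#'       \varepsilon(\beta) = -\frac{M_0 R \sin\beta}{E I_\omega}.}
#'
#' @param beta Angles in `[0, pi/4]`, rad.
#' @inheritParams curved_beam_intersection_profile
#' @return A tibble with columns `beta`, `u`, `epsilon`.
#' @export
arc_corner_profile <- function(beta, M0, R, wire) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > pi / 4 + 1e-12)) {
    rlang::abort("`beta` must lie within [0, pi/4].",
                 class = "tloop_domain_error")
  }
  EI <- wire_EI(wire)
  tibble::tibble(
    beta = beta,
    u = M0 * R^2 / EI * (cos(beta) - 1),
    epsilon = -M0 * R * sin(beta) / EI
  )
}

#' Vertical-arm restoring force F1
#'
#' The restoring force exerted by the deflected vertical arm. Two printed
#' variants of the stiffness denominator circulate in the source model:
#' `"full_arm"` uses \eqn{y^3}, `"arm_minus_radius"` (default) uses
#' \eqn{(y - R)^3} — the form fed into the final superposition. With the
#' default self-consistent coupling the intersection moment
#' \eqn{M_0 = -F_1 y} is eliminated exactly, giving the linear fixed point
#' \deqn{F_1 = \frac{3 m E I_z}{\mathrm{denom} + 3 y R (y - R)}.}
#' With `coupling = "explicit"` the caller supplies `M0` and
#' \eqn{F_1 = 3\,[m E I_z + M_0 R (y - R)]/\mathrm{denom}}.
#' Both variants collapse to the classic cantilever stiffness
#' \eqn{3 E I_z m / y^3} as R tends to 0.
#'
#' @param m_defl Maximum vertical-arm deflection, m (>= 0).
#' @param geom A [tloop_geometry()].
#' @param wire Archwire row.
#' @param f1_variant `"arm_minus_radius"` (default) or `"full_arm"`.
#' @param coupling `"self_consistent"` (default) or `"explicit"`.
#' @param M0 Intersection moment, N m; required when `coupling = "explicit"`.
#' @return Force F1 in newtons (non-negative for non-negative `m_defl`).
#' @export
vertical_arm_force <- function(m_defl, geom, wire,
                               f1_variant = c("arm_minus_radius", "full_arm"),
                               coupling = c("self_consistent", "explicit"),
                               M0 = NULL) {
  f1_variant <- match.arg(f1_variant)
  coupling <- match.arg(coupling)
  gw <- .unpack_gw(geom, wire)
  if (any(!is.finite(m_defl)) || any(m_defl < 0)) {
    rlang::abort("`m_defl` must be non-negative.", class = "tloop_input_error")
  }
  denom <- if (f1_variant == "full_arm") gw$y^3 else (gw$y - gw$R)^3
  if (coupling == "self_consistent") {
    stiff <- denom + 3 * gw$y * gw$R * (gw$y - gw$R)
    if (stiff <= 0) {
      rlang::abort("Singular geometry: denominator + 3yR(y - R) must be positive.",
                   class = "tloop_singular_geometry")
    }
    3 * m_defl * gw$EI / stiff
  } else {
    if (is.null(M0)) {
      rlang::abort("`M0` must be supplied when coupling = \"explicit\".",
                   class = "tloop_input_error")
    }
    if (denom <= 0) {
      rlang::abort("Singular geometry: zero stiffness denominator.",
                   class = "tloop_singular_geometry")
    }
    3 * (m_defl * gw$EI + M0 * gw$R * (gw$y - gw$R)) / denom
  }
}

#' Arc-portion restoring force F2
#'
#' The force released by the bent horizontal arm of the arc portion,
#' projected along the direction of tooth movement:
#' \deqn{F_2 = \frac{3 m E I_z \left(\sqrt{y^2 + m^2} - y\right)}
#'                  {(w - R)^3 \sqrt{y^2 + m^2}},}
#' i.e. the arm's bending force \eqn{G = 3 s E I_z/(w - R)^3} (with
#' \eqn{s = \sqrt{y^2+m^2} - y}) times the geometric sine factor
#' \eqn{m/\sqrt{y^2 + m^2}}. For small deflections
#' \eqn{F_2 \to 3 E I_z m^3 / (2 y^2 (w - R)^3)}.
#'
#' @inheritParams vertical_arm_force
#' @return Force F2 in newtons; zero iff `m_defl` is zero.
#' @export
arc_force <- function(m_defl, geom, wire) {
  gw <- .unpack_gw(geom, wire)
  if (any(!is.finite(m_defl)) || any(m_defl < 0)) {
    rlang::abort("`m_defl` must be non-negative.", class = "tloop_input_error")
  }
  if (gw$w <= gw$R) {
    rlang::abort("Singular geometry: w must exceed R.",
                 class = "tloop_singular_geometry")
  }
  hyp <- sqrt(gw$y^2 + m_defl^2)
  3 * m_defl * gw$EI * (hyp - gw$y) / ((gw$w - gw$R)^3 * hyp)
}

#' Total orthodontic force of the loaded T-loop
#'
#' Superposes the vertical-arm and arc-portion restoring forces,
#' \eqn{F_0 = F_1 + F_2}, for one or more clearance distances, and returns
#' the full decomposition. At fixed geometry and deflection, \eqn{F_0} is
#' linear in the bending stiffness \eqn{E I_z}, so force ratios across
#' wires equal their \eqn{E I_z} ratios.
#'
#' @param clearance_mm Clearance distances `b`, mm (>= 0). Vectorised.
#' @param geom A [tloop_geometry()].
#' @param wire Archwire row from [lookup_archwire()].
#' @param f1_variant,coupling,M0 Passed to [vertical_arm_force()].
#' @param clearance_mode Passed to [clearance_to_deflection()].
#' @param m_defl_mm Optional explicit maximum deflection, mm; overrides
#'   `clearance_mm` when supplied.
#' @return A tibble with one row per loading state: `clearance_mm`,
#'   `m_defl_mm`, `s_arc_mm`, `P_N`, `G_N`, `M0_Nm`, `F1_N`, `F2_N`, `F0_N`.
#' @export
#' @examples
#' tloop_force(c(0.3, 0.6, 1.2), tloop_geometry(), lookup_archwire("IV"))
tloop_force <- function(clearance_mm, geom = tloop_geometry(),
                        wire = lookup_archwire("IV"),
                        f1_variant = c("arm_minus_radius", "full_arm"),
                        clearance_mode = c("half", "full"),
                        coupling = c("self_consistent", "explicit"),
                        M0 = NULL, m_defl_mm = NULL) {
  f1_variant <- match.arg(f1_variant)
  clearance_mode <- match.arg(clearance_mode)
  coupling <- match.arg(coupling)
  if (is.null(m_defl_mm)) {
    m <- clearance_to_deflection(clearance_mm * 1e-3, mode = clearance_mode)
  } else {
    m <- m_defl_mm * 1e-3
    if (is.null(clearance_mm)) clearance_mm <- NA_real_
  }
  F1 <- vertical_arm_force(m, geom, wire, f1_variant = f1_variant,
                           coupling = coupling, M0 = M0)
  F2 <- arc_force(m, geom, wire)
  s <- arc_deformation(m, geom$y)
  G <- 3 * s * wire_EI(wire) / (geom$w - geom$R)^3
  tibble::tibble(
    clearance_mm = clearance_mm,
    m_defl_mm = m * 1e3,
    s_arc_mm = s * 1e3,
    P_N = F1,
    G_N = G,
    M0_Nm = intersection_moment(F1, geom$y),
    F1_N = F1,
    F2_N = F2,
    F0_N = F1 + F2
  )
}
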