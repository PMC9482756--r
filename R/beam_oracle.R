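# Independent finite-difference solvers for the two beam equations.
# These never call the closed forms in beam_mechanics.R; they exist to
# validate them, so they are kept deliberately plain: uniform grid,
# second-order central differences, direct sparse solve.

# Assemble and solve v'' + k*v = rhs(x) on [a, b] with clamped conditions
# (value + slope) at one end. k = 0 gives the straight beam, k = 1 the
# curved beam in its angular coordinate. The slope condition is imposed
# through a ghost node eliminated against the ODE row at the clamped end.
.solve_clamped_fd <- function(rhs, domain, k, bc_at, bc_value, bc_slope,
                              grid_n) {
  stopifnot(grid_n >= 32, length(domain) == 2L, domain[2] > domain[1])
  n <- grid_n + 1L                      # nodes
  h <- (domain[2] - domain[1]) / grid_n
  x <- seq(domain[1], domain[2], length.out = n)
  f <- rhs(x)

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  b <- numeric(n)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }

  interior <- 2:(n - 1L)
  add(interior, interior - 1L, rep(1 / h^2, length(interior)))
  add(interior, interior,      rep(-2 / h^2 + k, length(interior)))
  add(interior, interior + 1L, rep(1 / h^2, length(interior)))
  b[interior] <- f[interior]

  if (bc_at == "left") {
    # row 1: v_1 = value.  Row n: ODE at node 1 with ghost node eliminated
    # via (v_2 - v_0)/(2h) = slope  =>  v_0 = v_2 - 2 h slope.
    add(1L, 1L, 1); b[1L] <- bc_value
    add(n, 1L, -2 / h^2 + k); add(n, 2L, 2 / h^2)
    b[n] <- f[1L] + 2 * bc_slope / h
  } else {
    add(n, n, 1); b[n] <- bc_value
    add(1L, n, -2 / h^2 + k); add(1L, n - 1L, 2 / h^2)
    b[1L] <- f[n] - 2 * bc_slope / h
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  sol <- tryCatch(
    as.numeric(Matrix::solve(A, b)),
    error = function(e) rlang::abort("Singular finite-difference system.",
                                     class = "tloop_solver_error",
                                     parent = e))
  tibble::tibble(x = x, deflection = sol)
}

# Richardson error estimate for a second-order scheme: compare with the
# half-resolution solution on shared nodes.
.richardson_error <- function(fine, rhs, domain, k, bc_at, bc_value, bc_slope,
                              grid_n) {
  coarse <- .solve_clamped_fd(rhs, domain, k, bc_at, bc_value, bc_slope,
                              grid_n %/% 2L)
  shared <- seq(1L, nrow(fine), by = 2L)
  max(abs(fine$deflection[shared] - coarse$deflection)) / 3
}

#' Finite-difference solution of the straight-beam equation
#'
#' Solves \eqn{v''(x) = M(x)/(E I_z)} on a uniform grid with a clamped
#' (value + slope) condition at one end, by direct sparse solve of the
#' second-order central-difference system. This solver is the independent
#' oracle for the closed-form profiles in the mechanics layer and shares no
#' code with them.
#'
#' @param rhs Function of `x` returning the curvature load
#'   \eqn{M(x)/(E I_z)} (1/m).
#' @param domain Length-2 numeric, the axial interval, m.
#' @param bc_at `"left"` or `"right"`: the clamped end.
#' @param bc_value Deflection at the clamped end, m.
#' @param bc_slope Slope at the clamped end, rad.
#' @param grid_n Number of intervals (>= 32). Default 2048.
#' @return A tibble with columns `x`, `deflection`, carrying attribute
#'   `error_estimate` (Richardson extrapolation against the half grid).
#' @export
solve_straight_beam_bvp <- function(rhs, domain, bc_at = c("left", "right"),
                                    bc_value = 0, bc_slope = 0,
                                    grid_n = 2048) {
  bc_at <- match.arg(bc_at)
  out <- .solve_clamped_fd(rhs, domain, 0, bc_at, bc_value, bc_slope, grid_n)
  attr(out, "error_estimate") <-
    .richardson_error(out, rhs, domain, 0, bc_at, bc_value, bc_slope, grid_n)
  out
}

#' Finite-difference solution of the curved-beam equation
#'
#' Solves \eqn{u''(\alpha) + u = g(\alpha)} on an angular interval with a
#' clamped condition at one end, by the same second-order scheme as
#' [solve_straight_beam_bvp()]. For the intersection problem the clamp is
#' u = u' = 0 at \eqn{\pi/2}; the constant right-hand side is
#' \eqn{-M_0 R^2/(E I_\omega)}.
#'
#' @param rhs Function of the angle returning the right-hand side (m), or a
#'   single number for a constant load.
#' @param domain Length-2 numeric, the angular interval, rad.
#' @inheritParams solve_straight_beam_bvp
#' @return A tibble with columns `x` (angle) and `deflection` (m), with
#'   attribute `error_estimate`.
#' @export
solve_curved_beam_bvp <- function(rhs, domain = c(0, pi / 2),
                                  bc_at = c("right", "left"),
                                  bc_value = 0, bc_slope = 0,
                                  grid_n = 2048) {
  bc_at <- match.arg(bc_at)
  if (is.numeric(rhs) && length(rhs) == 1L) {
    const <- rhs
    rhs <- function(a) rep(const, length(a))
  }
  out <- .solve_clamped_fd(rhs, domain, 1, bc_at, bc_value, bc_slope, grid_n)
  attr(out, "error_estimate") <-
    .richardson_error(out, rhs, domain, 1, bc_at, bc_value, bc_slope, grid_n)
  out
}

#' Randomised agreement check between closed forms and the solver
#'
#' Draws random loop parameters and wires, evaluates the closed-form
#' vertical-arm and arc-horizontal profiles, and compares each with the
#' finite-difference solution of the same boundary-value problem. Also
#' evaluates the analytic residual of the two curved-beam closed forms in
#' their governing equation, and the discrepancy between the curved-beam
#' closed form and the angular solver.
#'
#' @param n_draws Number of random parameter draws.
#' @param seed Integer seed; the draw sequence is fully reproducible.
#' @param grid_n Grid resolution passed to the solvers.
#' @return A tibble with one row per draw and case: `draw`, `case`,
#'   `rel_err` (profile discrepancy relative to the profile's maximum
#'   amplitude) and `ode_residual` (curved-beam cases only, m).
#' @export
verify_beam_closed_forms <- function(n_draws = 100, seed = 42, grid_n = 2048) {
  cat_tbl <- archwire_catalog()
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_draws), function(i) {
      R_mm <- stats::runif(1, 0.5, 2)
      y_mm <- stats::runif(1, R_mm + 3, R_mm + 9)
      w_mm <- stats::runif(1, R_mm + 2, R_mm + 6)
      geom <- tloop_geometry(R_mm = R_mm, y_mm = y_mm, w_mm = w_mm,
                             h_mm = y_mm + 1)
      wire <- cat_tbl[sample.int(nrow(cat_tbl), 1L), ]
      P <- stats::runif(1, 0.1, 2)
      G <- stats::runif(1, 0.1, 2)
      EI <- wire_EI(wire)
      M0 <- intersection_moment(P, geom$y)

      # vertical arm: v'' = P (x - y)/EI, clamped at x = 0 with the
      # curved-segment boundary values
      num_v <- solve_straight_beam_bvp(
        rhs = function(x) P * (x - geom$y) / EI,
        domain = c(0, geom$y), bc_at = "left",
        bc_value = -M0 * geom$R^2 / EI,
        bc_slope = M0 * geom$R / EI,
        grid_n = grid_n)
      cf_v <- vertical_arm_profile(num_v$x, P, geom, wire)
      err_v <- max(abs(num_v$deflection - cf_v$deflection)) /
        max(abs(cf_v$deflection))

      # arc horizontal arm: v'' = G (l + R - w)/EI, clamped at l = 0
      span <- geom$w - geom$R
      num_a <- solve_straight_beam_bvp(
        rhs = function(l) G * (l + geom$R - geom$w) / EI,
        domain = c(0, span), bc_at = "left",
        bc_value = 0, bc_slope = 0, grid_n = grid_n)
      cf_a <- arc_horizontal_profile(num_a$x, G, geom, wire)
      err_a <- max(abs(num_a$deflection - cf_a$deflection)) /
        max(abs(cf_a$deflection))

      # curved beam at the intersection: solver vs closed form
      num_c <- solve_curved_beam_bvp(
        rhs = -M0 * geom$R^2 / EI, domain = c(0, pi / 2),
        bc_at = "right", bc_value = 0, bc_slope = 0, grid_n = grid_n)
      cf_c <- curved_beam_intersection_profile(num_c$x, M0, geom$R, wire)
      amp_c <- max(abs(cf_c$u))
      err_c <- if (amp_c > 0) max(abs(num_c$deflection - cf_c$u)) / amp_c else 0

      # analytic ODE residuals of the two curved-beam closed forms:
      # u'' + u - rhs, with u'' differentiated exactly
      a <- seq(0, pi / 2, length.out = 64)
      res_int <- max(abs(
        (-M0 * geom$R^2 / EI * sin(a)) +                    # u''
          M0 * geom$R^2 / EI * (sin(a) - 1) -               # + u
          (-M0 * geom$R^2 / EI)))                           # - rhs
      bgrid <- seq(0, pi / 4, length.out = 64)
      res_arc <- max(abs(
        (-M0 * geom$R^2 / EI * cos(bgrid)) +
          M0 * geom$R^2 / EI * (cos(bgrid) - 1) -
          (-M0 * geom$R^2 / EI)))

      tibble::tibble(
        draw = i,
        case = c("vertical_arm", "arc_horizontal", "curved_intersection",
                 "residual_intersection", "residual_arc_corner"),
        rel_err = c(err_v, err_a, err_c, NA_real_, NA_real_),
        ode_residual = c(NA_real_, NA_real_, NA_real_, res_int, res_arc)
      )
    })
  })
}
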