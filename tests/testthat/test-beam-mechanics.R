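test_that("clearance maps to deflection per the symmetric-loop convention", {
  expect_equal(clearance_to_deflection(0), 0)
  expect_equal(clearance_to_deflection(1.0), 0.5)
  expect_equal(clearance_to_deflection(1.0, mode = "full"), 1.0)
  expect_error(clearance_to_deflection(-0.1), class = "tloop_input_error")
})

test_that("intersection moment is -P y and linear in P", {
  expect_equal(intersection_moment(0, 0.01), 0)
  expect_equal(intersection_moment(1, 0.01), -0.01)
  expect_equal(intersection_moment(-2.5, 0.004), -intersection_moment(2.5, 0.004))
})

test_that("arc deformation follows the hypotenuse shortening", {
  expect_equal(arc_deformation(0, 0.008), 0)
  y <- 0.008
  expect_equal(arc_deformation(y, y), y * (sqrt(2) - 1))
  # small-deflection expansion s ~ m^2 / (2 y)
  m <- 1e-5 * y
  expect_equal(arc_deformation(m, y), m^2 / (2 * y), tolerance = 1e-4)
  # bounded by the deflection itself
  m <- seq(0, y, length.out = 20)
  s <- arc_deformation(m, y)
  expect_true(all(s >= 0 & s <= m + 1e-18))
})

test_that("vertical-arm profile honours its curved-segment boundary values", {
  g <- test_geom(); w <- wire_IV()
  P <- 1
  EI <- w$E_Pa * w$I_z_m4
  M0 <- -P * g$y
  prof <- vertical_arm_profile(c(0, g$y / 2, g$y), P, g, w)
  expect_equal(prof$deflection[1], -M0 * g$R^2 / EI)
  expect_equal(prof$rotation[1], M0 * g$R / EI)
  # zero load, zero profile
  z <- vertical_arm_profile(seq(0, g$y, length.out = 5), 0, g, w)
  expect_true(all(z$rotation == 0 & z$deflection == 0))
  expect_error(vertical_arm_profile(g$y * 1.5, P, g, w),
               class = "tloop_domain_error")
})

test_that("vertical-arm tip deflection collapses to the cantilever form as R -> 0", {
  w <- wire_IV()
  EI <- w$E_Pa * w$I_z_m4
  g0 <- tloop_geometry(R_mm = 1e-9, y_mm = 8, w_mm = 6, h_mm = 10)
  P <- 0.5
  tip <- vertical_arm_profile(g0$y, P, g0, w)
  expect_equal(abs(tip$deflection), P * g0$y^3 / (3 * EI), tolerance = 1e-6)
})

test_that("curved-beam closed forms satisfy their boundary conditions and ODE", {
  w <- wire_IV(); R <- 1e-3; M0 <- -0.005
  EI <- w$E_Pa * w$I_z_m4
  a <- seq(0, pi / 2, length.out = 33)
  prof <- curved_beam_intersection_profile(a, M0, R, w)
  expect_equal(prof$u[33], 0)
  expect_equal(prof$corner[33], 0, tolerance = 1e-15)
  expect_equal(prof$u[1], -M0 * R^2 / EI)
  expect_equal(prof$corner[1], M0 * R / EI)
  # pointwise ODE residual with exact second derivative
  resid <- (-M0 * R^2 / EI * sin(a)) + prof$u - (-M0 * R^2 / EI)
  expect_lt(max(abs(resid)), 1e-9)
  # zero moment, zero profile
  z <- curved_beam_intersection_profile(a, 0, R, w)
  expect_true(all(z$u == 0 & z$corner == 0))
  expect_error(curved_beam_intersection_profile(2, M0, R, w),
               class = "tloop_domain_error")

  b <- seq(0, pi / 4, length.out = 33)
  arc <- arc_corner_profile(b, M0, R, w)
  expect_equal(arc$u[1], 0)
  expect_equal(arc$epsilon[1], 0)
  resid_arc <- (-M0 * R^2 / EI * cos(b)) + arc$u - (-M0 * R^2 / EI)
  expect_lt(max(abs(resid_arc)), 1e-9)
})

test_that("arc horizontal profile is clamped at the junction with the stated tip value", {
  g <- test_geom(); w <- wire_I()
  EI <- w$E_Pa * w$I_z_m4
  G <- 0.8
  span <- g$w - g$R
  prof <- arc_horizontal_profile(c(0, span / 2, span), G, g, w)
  expect_equal(prof$rotation[1], 0)
  expect_equal(prof$deflection[1], 0)
  expect_equal(abs(prof$deflection[3]), abs(G) * span^3 / (3 * EI))
  z <- arc_horizontal_profile(span / 2, 0, g, w)
  expect_true(all(z$deflection == 0))
  expect_error(arc_horizontal_profile(span * 1.01, G, g, w),
               class = "tloop_domain_error")
})

test_that("self-consistent F1 equals the fixed point of the moment coupling", {
  g <- test_geom(); w <- wire_IV()
  EI <- w$E_Pa * w$I_z_m4
  m <- 0.5e-3
  for (variant in c("full_arm", "arm_minus_radius")) {
    denom <- if (variant == "full_arm") g$y^3 else (g$y - g$R)^3
    # independent oracle: scalar fixed-point iteration on
    # {M0 = -F1 y; F1 = 3 [m EI + M0 R (y - R)] / denom}
    F1 <- 0
    for (i in 1:200) {
      M0 <- -F1 * g$y
      F1 <- 3 * (m * EI + M0 * g$R * (g$y - g$R)) / denom
    }
    expect_equal(vertical_arm_force(m, g, w, f1_variant = variant), F1,
                 tolerance = 1e-12)
    # and explicit coupling reproduces the same value at that M0
    expect_equal(
      vertical_arm_force(m, g, w, f1_variant = variant,
                         coupling = "explicit", M0 = -F1 * g$y),
      F1, tolerance = 1e-12)
  }
  expect_equal(vertical_arm_force(0, g, w), 0)
  expect_error(vertical_arm_force(m, g, w, coupling = "explicit"),
               class = "tloop_input_error")
})

test_that("both F1 variants collapse to the classic cantilever stiffness as R -> 0", {
  w <- wire_IV()
  EI <- w$E_Pa * w$I_z_m4
  g0 <- tloop_geometry(R_mm = 1e-9, y_mm = 8, w_mm = 6, h_mm = 10)
  m <- 0.4e-3
  classic <- 3 * EI * m / g0$y^3
  expect_equal(vertical_arm_force(m, g0, w, f1_variant = "full_arm"),
               classic, tolerance = 1e-6)
  expect_equal(vertical_arm_force(m, g0, w, f1_variant = "arm_minus_radius"),
               classic, tolerance = 1e-6)
})

test_that("arc force matches its two-route computation and small-m limit", {
  g <- test_geom(); w <- wire_I()
  EI <- w$E_Pa * w$I_z_m4
  m <- 0.5e-3
  # route 1: printed closed form
  F2 <- arc_force(m, g, w)
  # route 2: bending force of the horizontal arm times the sine factor
  s <- sqrt(m^2 + g$y^2) - g$y
  G <- 3 * s * EI / (g$w - g$R)^3
  expect_equal(F2, G * m / sqrt(g$y^2 + m^2), tolerance = 1e-12)
  expect_equal(arc_force(0, g, w), 0)
  # cubic small-m behaviour: F2 / m^3 -> 3 EI / (2 y^2 (w - R)^3)
  m_small <- 1e-4 * g$y
  expect_equal(arc_force(m_small, g, w) / m_small^3,
               3 * EI / (2 * g$y^2 * (g$w - g$R)^3), tolerance = 1e-4)
  g_bad <- tloop_geometry(R_mm = 1, y_mm = 8, w_mm = 6, h_mm = 10)
  g_bad$w <- g_bad$R  # force the degenerate case past the constructor
  expect_error(arc_force(m, g_bad, w), class = "tloop_singular_geometry")
})

test_that("superposition holds exactly and the decomposition is consistent", {
  g <- test_geom()
  for (cn in c("I", "IV", "XI")) {
    w <- lookup_archwire(cn)
    dec <- tloop_force(seq(0.3, 1.2, by = 0.1), g, w)
    expect_identical(dec$F0_N, dec$F1_N + dec$F2_N)
    expect_equal(dec$M0_Nm, -dec$P_N * g$y)
    expect_true(all(dec$s_arc_mm >= 0))
  }
  expect_equal(tloop_force(0, g, wire_IV())$F0_N, 0)
})

test_that("total force is strictly increasing in deflection over random geometries", {
  withr::with_seed(7, {
    for (i in 1:25) {
      R_mm <- runif(1, 0.3, 2)
      g <- tloop_geometry(R_mm = R_mm, y_mm = runif(1, R_mm + 3, R_mm + 9),
                          w_mm = runif(1, R_mm + 2, R_mm + 6),
                          h_mm = 20)
      w <- lookup_archwire(sample(c("I", "III", "IV", "VII", "XI"), 1))
      m_grid <- seq(1e-5, g$y / 2, length.out = 40) * 1e3
      F0 <- tloop_force(NA, g, w, m_defl_mm = m_grid)$F0_N
      expect_true(all(diff(F0) > 0))
    }
  })
})

test_that("total force is linear in stiffness: material and section ratios", {
  g <- test_geom()
  b <- 0.8
  f_IV <- tloop_force(b, g, lookup_archwire("IV"))$F0_N
  f_VII <- tloop_force(b, g, lookup_archwire("VII"))$F0_N
  expect_equal(f_VII / f_IV, (20 / 14)^4, tolerance = 1e-9)
  # doubling E doubles the force
  w <- wire_IV()
  w2 <- w; w2$E_Pa <- 2 * w$E_Pa
  expect_equal(tloop_force(b, g, w2)$F0_N, 2 * f_IV, tolerance = 1e-12)
  # stainless beats Australian at equal section and state
  for (pair in list(c("IV", "VIII"), c("VII", "XI"))) {
    expect_gt(tloop_force(b, g, lookup_archwire(pair[1]))$F0_N,
              tloop_force(b, g, lookup_archwire(pair[2]))$F0_N)
  }
})
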