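all_laws <- function() list(
  material_law("M1", c(c = 17.43, a = 1.35, b = 5.93)),
  material_law("M2", c(c0 = 10, c1 = 15, c2 = 20)),
  material_law("M3", c(c0 = 0.29, c1 = 0.47, c2 = 55.39)),
  material_law("chordae_linear", c(C = 2000)),
  material_law("chordae_exp", c(a1 = 10, a2 = 30))
)

test_that("strain energy is zero at the reference state for every law", {
  for (law in all_laws()) {
    expect_equal(strain_energy(law, 3, 1), 0, info = law$law)
    expect_gte(strain_energy(law, 3.1, 1.1), 0)
  }
})

test_that("tension-only switch kills the fiber term in compression", {
  m1 <- mv_preset("M1", "anterior")
  expect_equal(strain_energy(m1, 3, 0.9), 0)   # matrix at I1=3 is also 0
  # energy must not depend on I4 below 1
  expect_equal(strain_energy(m1, 3.2, 0.8), strain_energy(m1, 3.2, 0.99))
  st <- biaxial_deformation(0.9, 1.02)  # fiber-axis compression
  for (law in all_laws()) {
    s <- cauchy_stress(law, st, "none")$sigma
    d <- energy_derivatives(law, st$I1, st$I4)
    expect_equal(d$dI4, 0, info = law$law)
    # stress reduces to the pure matrix term
    expect_equal(s, 2 * d$dI1 * tcrossprod(st$F), info = law$law)
  }
})

test_that("parameter validation rejects bad inputs", {
  expect_error(material_law("M9", c(c = 1)), "unknown law")
  expect_error(material_law("M1", c(c = -1, a = 1, b = 1)), "non-negative")
  expect_error(material_law("M1", c(1, 2, 3)), "needs parameters")
  expect_error(strain_energy(mv_preset("M1", "anterior"), 3, -1), "I4")
})

test_that("plane-stress multiplier elimination zeroes sigma33", {
  m1 <- mv_preset("M1", "anterior")
  s <- cauchy_stress(m1, biaxial_deformation(1, 1), "plane_stress")
  expect_equal(s$sigma, matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(s$lambda_mult, 2 * 17.43, tolerance = 1e-12)
  for (law in all_laws()) {
    s <- cauchy_stress(law, biaxial_deformation(1.12, 1.05), "plane_stress")
    expect_lt(abs(s$sigma[3, 3]), 1e-10)
    expect_equal(s$sigma, t(s$sigma), tolerance = 1e-10)
  }
})

test_that("uniaxial elimination zeroes both lateral stresses; closed forms", {
  lin <- material_law("chordae_linear", c(C = 1))
  s <- cauchy_stress(lin, uniaxial_deformation(1.1), "uniaxial")
  expect_equal(s$sigma[1, 1], 2 * (1.1^2 - 1 / 1.1), tolerance = 1e-12)
  expect_lt(max(abs(s$sigma[2, 2]), abs(s$sigma[3, 3])), 1e-12)
  ex <- material_law("chordae_exp", c(a1 = 10, a2 = 30))
  s <- cauchy_stress(ex, uniaxial_deformation(1), "uniaxial")
  expect_equal(s$sigma, matrix(0, 3, 3), tolerance = 1e-12)
})

test_that("analytic stress matches the finite-difference energy oracle", {
  set.seed(42)
  for (law in all_laws()) {
    for (k in 1:20) {
      F <- random_incompressible_F(tension = k %% 4 != 0)
      st <- valvefsi:::new_deformation_state(F, c(1, 0, 0))
      sa <- cauchy_stress(law, st, "none")$sigma
      sf <- fd_cauchy_stress(law, F, c(1, 0, 0))
      denom <- max(norm(sa, "F"), 1e-3)
      expect_lt(norm(sa - sf, "F") / denom, 1e-6)
    }
  }
})

test_that("stress is objective: sigma(RF) = R sigma(F) R^T", {
  set.seed(7)
  m3 <- mv_preset("M3", "anterior")
  for (k in 1:10) {
    F <- diag(c(1.15, 0.95, 1 / (1.15 * 0.95)))
    R <- random_rotation()
    s1 <- cauchy_stress(m3, valvefsi:::new_deformation_state(F, c(1, 0, 0)),
                        "none")$sigma
    s2 <- cauchy_stress(m3,
                        valvefsi:::new_deformation_state(R %*% F, c(1, 0, 0)),
                        "none")$sigma
    expect_equal(s2, R %*% s1 %*% t(R), tolerance = 1e-9)
  }
})

test_that("as-printed stress variants differ from the energy derivative", {
  m1 <- mv_preset("M1", "anterior")
  st <- biaxial_deformation(1.1, 1.05)
  s_deriv <- cauchy_stress(m1, st, "plane_stress")$sigma
  s_print <- cauchy_stress(m1, st, "plane_stress", as_printed = TRUE)$sigma
  expect_gt(abs(s_print[1, 1] - s_deriv[1, 1]), 1e-6)
  # printed variant is NOT the energy derivative; the default is
  fd <- fd_cauchy_stress(m1, st$F, st$a0)
  s_print_none <- cauchy_stress(m1, st, "none", as_printed = TRUE)$sigma
  s_deriv_none <- cauchy_stress(m1, st, "none")$sigma
  expect_gt(norm(s_print_none - fd, "F") / norm(fd, "F"), 1e-3)
  expect_lt(norm(s_deriv_none - fd, "F") / norm(fd, "F"), 1e-6)
  lin <- material_law("chordae_linear", c(C = 5))
  su <- uniaxial_deformation(1.1)
  expect_equal(cauchy_stress(lin, su, "uniaxial",
                             as_printed = TRUE)$sigma[1, 1],
               cauchy_stress(lin, su, "uniaxial")$sigma[1, 1] / 2,
               tolerance = 1e-12)
})

test_that("stress-stretch curves are monotone and match per-point stress", {
  proto <- biaxial_protocol(1.15, 12, paths = "equibiaxial")
  for (law in all_laws()[1:3]) {
    ds <- stress_stretch_curve(law, proto)
    expect_true(all(diff(ds$sigma11_kPa) > 0), info = law$law)
    s5 <- cauchy_stress(law, biaxial_deformation(ds$lambda1[5], ds$lambda2[5]),
                        "plane_stress")$sigma
    expect_equal(ds$sigma11_kPa[5], s5[1, 1], tolerance = 1e-12)
    expect_equal(ds$sigma22_kPa[5], s5[2, 2], tolerance = 1e-12)
  }
  # chordae exponential curve is convex in stretch
  ds <- stress_stretch_curve(material_law("chordae_exp", c(a1 = 10, a2 = 30)),
                             uniaxial_protocol(1.2, 30))
  expect_true(all(diff(diff(ds$sigma_kPa)) >= -1e-9))
  # single reference point gives a zero-stress row
  one <- stress_stretch_curve(mv_preset("M1", "anterior"),
                              stretch_protocol("biaxial",
                                               cbind(lambda1 = 1,
                                                     lambda2 = 1)))
  expect_equal(one$sigma11_kPa, 0)
  expect_equal(one$sigma22_kPa, 0)
})
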