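test_that("4-point delta kernel: partition of unity, symmetry, support", {
  for (r in seq(-0.5, 0.49, length.out = 23)) {
    expect_lt(abs(sum(peskin_delta(r + (-3:3))) - 1), 1e-12)
  }
  r <- seq(0, 1.99, length.out = 40)
  expect_equal(peskin_delta(r), peskin_delta(-r), tolerance = 1e-14)
  expect_equal(peskin_delta(c(2, 2.5, -3)), c(0, 0, 0))
  expect_equal(peskin_delta(0), 0.5, tolerance = 1e-14)
})

test_that("force spreading conserves total force; uniform-field interpolation", {
  grid <- eulerian_grid(32, 16, 4, 2)
  set.seed(3)
  pts <- cbind(runif(15, 0.5, 3.5), runif(15, 0.3, 1.7))
  Fn <- matrix(rnorm(30), 15, 2)
  f <- spread_force(grid, pts, Fn)
  expect_equal(sum(f$fu) * grid$h^2, sum(Fn[, 1]), tolerance = 1e-12)
  expect_equal(sum(f$fv) * grid$h^2, sum(Fn[, 2]), tolerance = 1e-12)
  # zero force -> zero field
  f0 <- spread_force(grid, pts, 0 * Fn)
  expect_equal(max(abs(f0$fu)), 0)
  # uniform velocity interpolates exactly (partition of unity)
  st <- grid_state(grid)
  st$u[] <- 2.5
  st$v[] <- -1.25
  vel <- interpolate_velocity(grid, st, pts)
  expect_equal(vel[, 1], rep(2.5, 15), tolerance = 1e-12)
  expect_equal(vel[, 2], rep(-1.25, 15), tolerance = 1e-12)
  # node outside the domain errors
  expect_error(spread_force(grid, rbind(c(-0.1, 1)), rbind(c(1, 0))),
               "outside")
})

test_that("spreading and interpolation are exact adjoints", {
  grid <- eulerian_grid(24, 24, 2, 2)
  set.seed(8)
  pts <- cbind(runif(12, 0.3, 1.7), runif(12, 0.3, 1.7))
  Fn <- matrix(rnorm(24), 12, 2)
  st <- grid_state(grid)
  st$u[] <- rnorm(length(st$u))
  st$v[] <- rnorm(length(st$v))
  f <- spread_force(grid, pts, Fn)
  lhs <- (sum(f$fu * st$u) + sum(f$fv * st$v)) * grid$h^2
  vel <- interpolate_velocity(grid, st, pts)
  rhs <- sum(Fn * vel)
  expect_equal(lhs, rhs, tolerance = 1e-12 * max(1, abs(rhs)))
})

test_that("linear velocity field is interpolated with small moment error", {
  grid <- eulerian_grid(32, 32, 2, 2)
  st <- grid_state(grid)
  yu <- (col(st$u) - 0.5) * grid$h
  st$u <- yu                       # u = y
  pts <- cbind(runif(10, 0.5, 1.5), runif(10, 0.5, 1.5))
  vel <- interpolate_velocity(grid, st, pts)
  # the 4-point kernel has exact zeroth and first moments on uniform grids
  expect_equal(vel[, 1], pts[, 2], tolerance = 1e-10)
})

test_that("internal forces are the exact negative energy gradient", {
  set.seed(21)
  X0 <- cbind(seq(0, 1, length.out = 9), rep(0.5, 9))
  struct <- fiber_structure(
    X0, mv_preset("M1", "anterior"), thickness = 0.1, kb = 0.05,
    anchors = list(list(node = 1L, point = c(0, 0.5), ka = 1e4)),
    tethers = list(list(node = 9L, point = c(1.6, 0.5), L0 = 0.5,
                        law = chordae_linear_default(), area = 0.02)),
    walls = list(y = c(0.3, 0.9), k = 5e3, range = 0.25),
    midplane = list(y = 0.5, k = 4e3, side = 1))
  pos <- X0 + 0.03 * matrix(rnorm(18), 9, 2)
  f <- internal_force(struct, pos)
  g <- fd_energy_gradient(struct, pos)
  expect_lt(max(abs(f + g)) / max(abs(g)), 1e-6)

  # undeformed, anchor-consistent mesh carries no force
  struct0 <- fiber_structure(X0, mv_preset("M1", "anterior"), kb = 0.05)
  expect_equal(internal_force(struct0, X0), matrix(0, 9, 2),
               tolerance = 1e-12)
  # rigid translation of a free structure: zero force, zero net torque
  posT <- X0 + rep(c(0.2, -0.1), each = 9)
  expect_equal(internal_force(struct0, posT), matrix(0, 9, 2),
               tolerance = 1e-10)
  posR <- pos
  fR <- internal_force(struct0, posR)
  expect_lt(abs(sum(fR)), 1e-8 * max(abs(fR)))          # net force
  torque <- sum(posR[, 1] * fR[, 2] - posR[, 2] * fR[, 1])
  expect_lt(abs(torque), 1e-8 * max(abs(fR)))           # net torque
  expect_error(internal_force(struct0, X0 * 0), "degenerate")
})

test_that("quiescent fluid stays quiescent; projection is divergence-free", {
  grid <- eulerian_grid(16, 8, 4, 2)
  st <- grid_state(grid)
  st2 <- ns_step(grid, st, NULL, dt = 1e-3, bc = list(p_in = 0, p_out = 0))
  expect_equal(max(abs(st2$u)), 0, tolerance = 1e-14)
  expect_equal(max(abs(st2$v)), 0, tolerance = 1e-14)

  set.seed(5)
  st$u[] <- rnorm(length(st$u), sd = 1)
  st$v[, 2:8] <- rnorm(length(st$v[, 2:8]), sd = 1)
  dt <- 0.2 * grid$rho * grid$h^2 / (4 * grid$mu) /
    (max(abs(st$u)) * 50 / grid$h + 1) # conservative
  dt <- min(dt, 0.4 * grid$h / max(abs(st$u), abs(st$v)))
  st2 <- ns_step(grid, st, NULL, dt = dt, bc = list(p_in = 10, p_out = 0))
  div <- divergence(grid, st2)
  expect_lt(max(abs(div)) * grid$h / max(abs(st2$u)), 1e-10)
})

test_that("CFL violation aborts with a suggested time step", {
  grid <- eulerian_grid(16, 8, 4, 2)
  st <- grid_state(grid)
  st$u[] <- 100
  expect_error(ns_step(grid, st, NULL, dt = 1, bc = list(p_in = 0, p_out = 0)),
               "CFL")
})

test_that("steady pressure drop drives the analytic Poiseuille profile", {
  # moderate resolution for the routine suite; the acceptance run uses
  # the full 64-cell channel height
  grid <- eulerian_grid(8, 32, 0.5, 2, rho = 1, mu = 1)
  st <- grid_state(grid)
  dp <- 1.0
  dt <- 0.45 * grid$rho * grid$h^2 / (4 * grid$mu)
  t_end <- 2.0   # ~ half a viscous time H^2/nu; decay factor exp(-pi^2 t/4)
  nstep <- ceiling(t_end / dt)
  for (k in seq_len(nstep))
    st <- ns_step(grid, st, NULL, dt, bc = list(p_in = dp, p_out = 0))
  exact <- poiseuille_exact(grid, dp)
  prof <- st$u[4, ]
  expect_lt(max(abs(prof - exact)) / max(exact), 0.02)
})
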