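# 2D immersed-boundary / finite-element demonstrator.
#
# Incompressible Navier-Stokes on a staggered MAC grid (u at x-faces, v at
# y-faces, p at cell centres), explicit upwind advection + explicit
# diffusion + pressure projection, channel geometry: no-slip walls at
# y = 0 and y = Ly, pressure (Dirichlet) conditions at the inlet x = 0 and
# outlet x = Lx.  The immersed structure is a set of fiber-aligned elastic
# curves coupled through the standard 4-point regularised delta function.
# CGS units throughout: cm, s, g, dyn/cm^2.

#' Unit conversion constants
#'
#' `1 mmHg = 0.13332 kPa = 1333.22 dyn/cm^2`; `1 kPa = 1e4 dyn/cm^2`.
#' @name units
#' @export
MMHG_TO_KPA <- 0.133322

#' @rdname units
#' @export
MMHG_TO_DYN_CM2 <- 1333.22

#' @rdname units
#' @export
KPA_TO_DYN_CM2 <- 1e4

# ---- Eulerian grid ---------------------------------------------------------

#' Staggered Eulerian grid for the 2D channel
#'
#' @param nx,ny number of cells along x (streamwise) and y (cross-channel).
#' @param Lx,Ly domain extents in cm; cells must be square
#'   (`Lx/nx == Ly/ny`).
#' @param rho fluid density (g/cm^3, default 1.0, typical for blood).
#' @param mu dynamic viscosity (g/(cm s), default 0.04, typical for blood).
#' @return An `eulerian_grid` object.  Velocity `u` lives on a
#'   `(nx+1) x ny` array of x-faces, `v` on `nx x (ny+1)` y-faces, `p` on
#'   `nx x ny` cell centres.
#' @export
eulerian_grid <- function(nx, ny, Lx, Ly, rho = 1.0, mu = 0.04) {
  h1 <- Lx / nx
  h2 <- Ly / ny
  if (abs(h1 - h2) > 1e-12 * max(h1, h2))
    stop("grid cells must be square: choose nx/ny = Lx/Ly")
  g <- structure(list(nx = as.integer(nx), ny = as.integer(ny),
                      Lx = Lx, Ly = Ly, h = h1, rho = rho, mu = mu,
                      cache = new.env(parent = emptyenv())),
                 class = "eulerian_grid")
  g
}

#' @export
print.eulerian_grid <- function(x, ...) {
  cat(sprintf("Eulerian MAC grid %d x %d, h = %.4g cm, domain %g x %g cm\n",
              x$nx, x$ny, x$h, x$Lx, x$Ly))
  cat(sprintf("  rho = %g g/cm^3, mu = %g g/(cm s)\n", x$rho, x$mu))
  invisible(x)
}

#' Zero-initialised field state for a grid
#' @param grid an `eulerian_grid`.
#' @return List with matrices `u`, `v`, `p`.
#' @export
grid_state <- function(grid) {
  list(u = matrix(0, grid$nx + 1, grid$ny),
       v = matrix(0, grid$nx, grid$ny + 1),
       p = matrix(0, grid$nx, grid$ny))
}

# Pressure-Poisson operator with Dirichlet ghosts at inlet/outlet and
# Neumann at the walls; factorised once per grid and cached.
poisson_factor <- function(grid) {
  if (!is.null(grid$cache$chol)) return(grid$cache$chol)
  nx <- grid$nx; ny <- grid$ny
  id <- function(i, j) i + (j - 1L) * nx
  ii <- jj <- xx <- list()
  k <- 0L
  add <- function(a, b, val) {
    k <<- k + 1L; ii[[k]] <<- a; jj[[k]] <<- b; xx[[k]] <<- val
  }
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    c0 <- 0
    if (i > 1) { add(id(i, j), id(i - 1L, j), 1); c0 <- c0 - 1 }
    else c0 <- c0 - 2                       # Dirichlet ghost at inlet
    if (i < nx) { add(id(i, j), id(i + 1L, j), 1); c0 <- c0 - 1 }
    else c0 <- c0 - 2                       # Dirichlet ghost at outlet
    if (j > 1) { add(id(i, j), id(i, j - 1L), 1); c0 <- c0 - 1 }
    if (j < ny) { add(id(i, j), id(i, j + 1L), 1); c0 <- c0 - 1 }
    add(id(i, j), id(i, j), c0)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nx * ny, nx * ny)) / grid$h^2
  grid$cache$chol <- Matrix::Cholesky(Matrix::forceSymmetric(-A),
                                      LDL = FALSE, perm = TRUE)
  grid$cache$chol
}

#' Discrete divergence of a velocity field
#' @param grid an `eulerian_grid`.
#' @param state a grid state (list with `u`, `v`).
#' @return `nx x ny` matrix of cell-centred divergence (1/s).
#' @export
divergence <- function(grid, state) {
  nx <- grid$nx; ny <- grid$ny
  du <- state$u[2:(nx + 1), , drop = FALSE] - state$u[1:nx, , drop = FALSE]
  dv <- state$v[, 2:(ny + 1), drop = FALSE] - state$v[, 1:ny, drop = FALSE]
  (du + dv) / grid$h
}

# Pad u with ghosts: zero-gradient in x (open ends), no-slip reflection in y.
pad_u <- function(u) {
  n <- nrow(u)
  up <- rbind(u[1, ], u, u[n, ])
  cbind(-up[, 1], up, -up[, ncol(up)])
}

# Pad v with ghosts: zero-gradient in x; wall rows are prescribed (v = 0).
pad_v <- function(v) {
  n <- nrow(v)
  vp <- rbind(v[1, ], v, v[n, ])
  m <- ncol(vp)
  cbind(2 * vp[, 1] - vp[, 2], vp, 2 * vp[, m] - vp[, m - 1])
}

#' One explicit projection step of the incompressible Navier-Stokes solver
#'
#' Explicit first-order upwind advection and explicit diffusion form a
#' provisional velocity; a pressure Poisson solve (Dirichlet pressure at
#' inlet/outlet from `bc`, homogeneous Neumann at the no-slip walls)
#' projects it onto a discretely divergence-free field.  Aborts with a
#' suggested time step if `dt` violates the advective or viscous stability
#' bound.
#'
#' @param grid an `eulerian_grid`.
#' @param state list with `u`, `v` (and optionally `p`).
#' @param force body force as a list `fu`, `fv` on the velocity grids
#'   (dyn/cm^3), or `NULL`.
#' @param dt time step (s).
#' @param bc list with inlet/outlet pressures `p_in`, `p_out` (dyn/cm^2).
#' @return Updated state (with the new pressure in `p`).
#' @export
ns_step <- function(grid, state, force = NULL, dt,
                    bc = list(p_in = 0, p_out = 0)) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  rho <- grid$rho; mu <- grid$mu
  u <- state$u; v <- state$v

  umax <- max(abs(u), abs(v), 1e-12)
  dt_adv <- h / umax
  dt_visc <- rho * h^2 / (4 * mu)
  if (dt > min(dt_adv, dt_visc))
    stop(sprintf(
      "CFL violation: dt = %.3g exceeds stability bound %.3g (try dt = %.3g)",
      dt, min(dt_adv, dt_visc), 0.5 * min(dt_adv, dt_visc)))

  up <- pad_u(u)   # (nx+3) x (ny+2); interior offset +1 in both dims
  vp <- pad_v(v)   # (nx+2) x (ny+3)

  iu <- 2:(nx + 2); ju <- 2:(ny + 1)     # u interior in padded coords
  iv <- 2:(nx + 1); jv <- 2:(ny + 2)     # v interior in padded coords

  # -- u momentum --------------------------------------------------------
  uc <- up[iu, ju]
  # v averaged to u points (clip columns at the open ends)
  vxm <- pmax(iu - 2L, 1L); vxp <- pmin(iu - 1L, nx)
  vbar <- 0.25 * (v[vxm, 1:ny, drop = FALSE] + v[vxp, 1:ny, drop = FALSE] +
                  v[vxm, 2:(ny + 1), drop = FALSE] +
                  v[vxp, 2:(ny + 1), drop = FALSE])
  dudx_m <- (uc - up[iu - 1, ju]) / h
  dudx_p <- (up[iu + 1, ju] - uc) / h
  dudy_m <- (uc - up[iu, ju - 1]) / h
  dudy_p <- (up[iu, ju + 1] - uc) / h
  pu <- uc > 0; pv <- vbar > 0
  adv_u <- uc * (pu * dudx_m + (!pu) * dudx_p) +
    vbar * (pv * dudy_m + (!pv) * dudy_p)
  lap_u <- (up[iu + 1, ju] + up[iu - 1, ju] + up[iu, ju + 1] +
            up[iu, ju - 1] - 4 * uc) / h^2
  fu <- if (is.null(force)) 0 else force$fu
  ustar <- u + dt * (-adv_u + (mu / rho) * lap_u + fu / rho)

  # -- v momentum (interior y-faces only; wall faces stay 0) -------------
  vc <- vp[iv, jv]
  ubar <- 0.25 * (u[1:nx, pmax(jv - 2L, 1L), drop = FALSE] +
                  u[2:(nx + 1), pmax(jv - 2L, 1L), drop = FALSE] +
                  u[1:nx, pmin(jv - 1L, ny), drop = FALSE] +
                  u[2:(nx + 1), pmin(jv - 1L, ny), drop = FALSE])
  dvdx_m <- (vc - vp[iv - 1, jv]) / h
  dvdx_p <- (vp[iv + 1, jv] - vc) / h
  dvdy_m <- (vc - vp[iv, jv - 1]) / h
  dvdy_p <- (vp[iv, jv + 1] - vc) / h
  qu <- ubar > 0; qv <- vc > 0
  adv_v <- ubar * (qu * dvdx_m + (!qu) * dvdx_p) +
    vc * (qv * dvdy_m + (!qv) * dvdy_p)
  lap_v <- (vp[iv + 1, jv] + vp[iv - 1, jv] + vp[iv, jv + 1] +
            vp[iv, jv - 1] - 4 * vc) / h^2
  fv <- if (is.null(force)) 0 else force$fv
  vstar <- v + dt * (-adv_v + (mu / rho) * lap_v + fv / rho)
  vstar[, 1] <- 0
  vstar[, ny + 1] <- 0

  # -- pressure projection ----------------------------------------------
  div_star <- divergence(grid, list(u = ustar, v = vstar))
  rhs <- (rho / dt) * as.vector(div_star)
  bcvec <- matrix(0, nx, ny)
  bcvec[1, ] <- bcvec[1, ] - 2 * bc$p_in / h^2
  bcvec[nx, ] <- bcvec[nx, ] - 2 * bc$p_out / h^2
  rhs <- rhs + as.vector(bcvec)
  p <- matrix(as.numeric(Matrix::solve(poisson_factor(grid), -rhs)), nx, ny)

  dpdx <- matrix(0, nx + 1, ny)
  dpdx[2:nx, ] <- (p[2:nx, ] - p[1:(nx - 1), ]) / h
  dpdx[1, ] <- 2 * (p[1, ] - bc$p_in) / h
  dpdx[nx + 1, ] <- 2 * (bc$p_out - p[nx, ]) / h
  unew <- ustar - (dt / rho) * dpdx

  dpdy <- matrix(0, nx, ny + 1)
  dpdy[, 2:ny] <- (p[, 2:ny] - p[, 1:(ny - 1)]) / h
  vnew <- vstar - (dt / rho) * dpdy
  vnew[, 1] <- 0
  vnew[, ny + 1] <- 0

  list(u = unew, v = vnew, p = p)
}

# ---- regularised delta coupling -------------------------------------------

#' The 4-point regularised delta kernel
#'
#' The standard 4-point immersed-boundary kernel: compact support
#' `|r| < 2`, even, and an exact partition of unity
#' `sum_j phi(r - j) = 1` for every real `r`.
#'
#' @param r offset in grid cells (vectorised).
#' @return Kernel values.
#' @export
peskin_delta <- function(r) {
  a <- abs(r)
  out <- numeric(length(r))
  i1 <- a < 1
  out[i1] <- (3 - 2 * a[i1] + sqrt(1 + 4 * a[i1] - 4 * a[i1]^2)) / 8
  i2 <- a >= 1 & a < 2
  out[i2] <- (5 - 2 * a[i2] - sqrt(-7 + 12 * a[i2] - 4 * a[i2]^2)) / 8
  out
}

# Stencil indices and weights for points on a staggered component grid.
# ox, oy: physical coordinate of array index (1,1) in units of h.
ib_stencil <- function(grid, pts, ox, oy, nmax_x, nmax_y) {
  h <- grid$h
  tol <- 0.05 * h   # boundary-attached nodes may drift by rounding
  out <- pts[, 1] < -tol | pts[, 1] > grid$Lx + tol |
    pts[, 2] < -tol | pts[, 2] > grid$Ly + tol
  if (any(out))
    stop(sprintf("structure node outside the fluid domain (first: %s)",
                 paste(signif(pts[which(out)[1], ], 4), collapse = ", ")))
  pts[, 1] <- pmin(pmax(pts[, 1], 0), grid$Lx)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), grid$Ly)
  gx <- pts[, 1] / h + 1 - ox
  gy <- pts[, 2] / h + 1 - oy
  ix <- as.integer(floor(gx)) + rep(c(-1L, 0L, 1L, 2L), each = nrow(pts))
  iy <- as.integer(floor(gy)) + rep(c(-1L, 0L, 1L, 2L), each = nrow(pts))
  wx <- peskin_delta(gx - ix)
  wy <- peskin_delta(gy - iy)
  dim(ix) <- dim(wx) <- c(nrow(pts), 4L)
  dim(iy) <- dim(wy) <- c(nrow(pts), 4L)
  # drop out-of-range stencil contributions (wall-adjacent nodes); the raw
  # indices are kept and handled by a guard band / clamping downstream
  wx[ix < 1 | ix > nmax_x] <- 0
  wy[iy < 1 | iy > nmax_y] <- 0
  list(ix = ix, iy = iy, wx = wx, wy = wy,
       nx = as.integer(nmax_x), ny = as.integer(nmax_y))
}

# Per-node 4x4 block accumulation into a guard-banded array (the stencil
# of an in-domain node reaches at most 2 cells past the array edge); the
# indices within one node's block are 4 consecutive integers, so block
# assignment never collides.
scatter_add <- function(mat, st, vals) {
  acc <- matrix(0, st$nx + 4L, st$ny + 4L)
  for (k in seq_along(vals)) {
    if (vals[k] == 0) next
    acc[st$ix[k, ] + 2L, st$iy[k, ] + 2L] <-
      acc[st$ix[k, ] + 2L, st$iy[k, ] + 2L] +
      outer(st$wx[k, ], st$wy[k, ]) * vals[k]
  }
  mat + acc[3:(st$nx + 2L), 3:(st$ny + 2L)]
}

gather <- function(mat, st) {
  nr <- nrow(mat)
  ix <- pmin(pmax(st$ix, 1L), st$nx)   # zero-weight entries: index arbitrary
  iy <- pmin(pmax(st$iy, 1L), st$ny)
  out <- numeric(nrow(ix))
  for (k1 in 1:4) for (k2 in 1:4) {
    li <- ix[, k1] + (iy[, k2] - 1L) * nr
    out <- out + st$wx[, k1] * st$wy[, k2] * mat[li]
  }
  out
}

#' Spread Lagrangian nodal forces onto the Eulerian grid
#'
#' `f(x) = sum_k F_k delta_h(x - X_k)` with the tensor-product 4-point
#' kernel; the discrete spreading conserves total force
#' (`sum f h^2 = sum F`) whenever the kernel support lies inside the
#' domain (contributions beyond a wall are clipped).
#'
#' @param grid an `eulerian_grid`.
#' @param pts `n x 2` matrix of node positions (cm).
#' @param forces `n x 2` matrix of nodal forces (dyn per unit depth).
#' @return List `fu`, `fv`: body-force densities (dyn/cm^3) on the u- and
#'   v-grids.
#' @export
spread_force <- function(grid, pts, forces) {
  pts <- as.matrix(pts); forces <- as.matrix(forces)
  stopifnot(ncol(pts) == 2, all(dim(forces) == dim(pts)))
  stu <- ib_stencil(grid, pts, ox = 0, oy = 0.5, grid$nx + 1L, grid$ny)
  stv <- ib_stencil(grid, pts, ox = 0.5, oy = 0, grid$nx, grid$ny + 1L)
  fu <- scatter_add(matrix(0, grid$nx + 1, grid$ny), stu,
                    forces[, 1] / grid$h^2)
  fv <- scatter_add(matrix(0, grid$nx, grid$ny + 1), stv,
                    forces[, 2] / grid$h^2)
  list(fu = fu, fv = fv)
}

#' Interpolate the Eulerian velocity to Lagrangian nodes
#'
#' `U_k = sum_x u(x) delta_h(x - X_k) h^2`, the exact adjoint of
#' [spread_force()] with the same kernel, so
#' `<spread(F), u> h^2 = <F, interp(u)>` to machine precision.
#'
#' @param grid an `eulerian_grid`.
#' @param state grid state with `u`, `v`.
#' @param pts `n x 2` matrix of node positions (cm).
#' @return `n x 2` matrix of nodal velocities (cm/s).
#' @export
interpolate_velocity <- function(grid, state, pts) {
  pts <- as.matrix(pts)
  stu <- ib_stencil(grid, pts, ox = 0, oy = 0.5, grid$nx + 1L, grid$ny)
  stv <- ib_stencil(grid, pts, ox = 0.5, oy = 0, grid$nx, grid$ny + 1L)
  cbind(gather(state$u, stu), gather(state$v, stv))
}
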