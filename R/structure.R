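# Fiber-aligned elastic curves for the 2D demonstrator.
#
# A leaflet is a 1D chain of nodes; each line element carries one of the
# 3D constitutive laws through a plane-strain completion of its stretch:
# the element stretch lambda gives I4 = lambda^2 (fiber along the element)
# and, with out-of-plane stretch 1 and in-plane incompressibility,
# I1 = lambda^2 + 1/lambda^2 + 1.  Element energy is
# Psi(I1, I4) * L0 * thickness (per unit depth), so the 3D kPa
# parameterisations plug in unchanged.  A small discrete bending energy
# regularises the otherwise tension-only chain, anchors pin attachment
# nodes by stiff position penalties, and optional tethers (chordae
# analogues) connect chosen nodes to fixed points with a chordae law,
# slack in compression.

#' Fiber-aligned elastic curve (leaflet analogue)
#'
#' @param X0 `n x 2` matrix of reference node positions (cm), ordered
#'   along the curve.
#' @param law a `material_law` for the element response.
#' @param thickness effective cross-section per unit depth (cm).
#' @param kb bending modulus (erg cm per unit depth); 0 disables bending.
#' @param anchors list of `list(node =, point = c(x, y), ka =)` stiff
#'   position penalties (ka in dyn/cm per unit depth).
#' @param tethers list of
#'   `list(node =, point = c(x, y), L0 =, law =, area =)` chordae-like
#'   cords from a node to a fixed point; slack (zero energy) when shorter
#'   than the rest length `L0`.
#' @param walls optional wall-contact penalty (the housing):
#'   `list(y = c(y_lo, y_hi), k =, range =)` — a quadratic repulsion
#'   acting on nodes closer than `range` to either wall.
#' @param midplane optional coaptation-plane penalty standing in for
#'   leaflet-leaflet contact in symmetric valve geometries:
#'   `list(y =, k =, side = +1 or -1)` — quadratic repulsion once nodes
#'   cross `y` from the structure's side (`side = +1` for a structure
#'   living below the plane).
#' @return A `fiber_structure` object.
#' @export
fiber_structure <- function(X0, law, thickness = 0.1, kb = 0,
                            anchors = list(), tethers = list(),
                            walls = NULL, midplane = NULL) {
  X0 <- as.matrix(X0)
  stopifnot(ncol(X0) == 2, nrow(X0) >= 2, inherits(law, "material_law"))
  L0 <- sqrt(rowSums((X0[-1, , drop = FALSE] -
                      X0[-nrow(X0), , drop = FALSE])^2))
  if (any(L0 <= 0)) stop("degenerate reference element (zero length)")
  for (tt in tethers)
    stopifnot(inherits(tt$law, "material_law"), tt$L0 > 0, tt$area > 0)
  structure(list(X0 = X0, n = nrow(X0), law = law, thickness = thickness,
                 L0 = L0, kb = kb, anchors = anchors, tethers = tethers,
                 walls = walls, midplane = midplane),
            class = "fiber_structure")
}

#' @export
print.fiber_structure <- function(x, ...) {
  cat(sprintf(
    "Fiber structure: %d nodes, law %s, thickness %g cm, kb = %g\n",
    x$n, x$law$law, x$thickness, x$kb))
  cat(sprintf("  %d anchor(s), %d tether(s)\n",
              length(x$anchors), length(x$tethers)))
  invisible(x)
}

# Element energy density per reference length (dyn, i.e. erg/cm) and its
# derivative w.r.t. stretch, for the plane-strain completed invariants.
element_w <- function(law, lambda, thickness) {
  I1 <- lambda^2 + 1 / lambda^2 + 1
  I4 <- lambda^2
  w <- strain_energy(law, I1, I4) * KPA_TO_DYN_CM2 * thickness
  d <- energy_derivatives(law, I1, I4)
  dw <- (d$dI1 * (2 * lambda - 2 / lambda^3) + d$dI4 * 2 * lambda) *
    KPA_TO_DYN_CM2 * thickness
  list(w = w, dw = dw)
}

# Tether (cord) energy: same 1D completion but slack below rest length.
# w is the total cord energy; dw its derivative w.r.t. the cord stretch.
tether_w <- function(tether, len) {
  lambda <- len / tether$L0
  if (lambda <= 1) return(list(w = 0, dw = 0))
  ew <- element_w(tether$law, lambda, tether$area)
  list(w = ew$w * tether$L0, dw = ew$dw * tether$L0)
}

#' Total elastic energy of a fiber structure
#'
#' Stretch energy of the chain elements plus discrete bending energy,
#' anchor penalties and tether energies, all per unit depth (erg/cm).
#'
#' @param struct a `fiber_structure`.
#' @param pos `n x 2` matrix of current node positions (defaults to the
#'   reference positions).
#' @return Scalar energy.
#' @export
elastic_energy <- function(struct, pos = struct$X0) {
  pos <- as.matrix(pos)
  d <- pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len <= 1e-12)) stop("inverted/degenerate element")
  lambda <- len / struct$L0
  E <- sum(element_w(struct$law, lambda, struct$thickness)$w * struct$L0)
  if (struct$kb > 0 && struct$n >= 3) {
    ds <- mean(struct$L0)
    b <- pos[1:(struct$n - 2), , drop = FALSE] -
      2 * pos[2:(struct$n - 1), , drop = FALSE] +
      pos[3:struct$n, , drop = FALSE]
    E <- E + struct$kb / (2 * ds^3) * sum(b^2)
  }
  for (a in struct$anchors)
    E <- E + a$ka / 2 * sum((pos[a$node, ] - a$point)^2)
  for (tt in struct$tethers) {
    len_t <- sqrt(sum((pos[tt$node, ] - tt$point)^2))
    E <- E + tether_w(tt, len_t)$w
  }
  if (!is.null(struct$walls)) {
    w <- struct$walls
    pen_lo <- pmax(0, (w$y[1] + w$range) - pos[, 2])
    pen_hi <- pmax(0, pos[, 2] - (w$y[2] - w$range))
    E <- E + w$k / 2 * sum(pen_lo^2 + pen_hi^2)
  }
  if (!is.null(struct$midplane)) {
    m <- struct$midplane
    pen <- pmax(0, m$side * (pos[, 2] - m$y))
    E <- E + m$k / 2 * sum(pen^2)
  }
  E
}

#' Internal nodal forces of a fiber structure
#'
#' Exactly the negative gradient of [elastic_energy()] with respect to the
#' node positions.  For a free structure (no anchors or tethers) the net
#' force and net torque vanish by frame indifference of the energy.
#'
#' @inheritParams elastic_energy
#' @return `n x 2` matrix of nodal forces (dyn per unit depth).
#' @export
internal_force <- function(struct, pos = struct$X0) {
  pos <- as.matrix(pos)
  n <- struct$n
  f <- matrix(0, n, 2)
  d <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len <= 1e-12)) stop("inverted/degenerate element")
  lambda <- len / struct$L0
  ten <- element_w(struct$law, lambda, struct$thickness)$dw  # dW/dlambda
  that <- d / len
  felem <- ten * that                       # force pulling node i towards i+1
  f[-n, ] <- f[-n, ] + felem
  f[-1, ] <- f[-1, ] - felem
  if (struct$kb > 0 && n >= 3) {
    ds <- mean(struct$L0)
    cb <- struct$kb / ds^3
    b <- pos[1:(n - 2), , drop = FALSE] - 2 * pos[2:(n - 1), , drop = FALSE] +
      pos[3:n, , drop = FALSE]
    g <- matrix(0, n, 2)
    g[1:(n - 2), ] <- g[1:(n - 2), ] + cb * b
    g[2:(n - 1), ] <- g[2:(n - 1), ] - 2 * cb * b
    g[3:n, ] <- g[3:n, ] + cb * b
    f <- f - g
  }
  for (a in struct$anchors)
    f[a$node, ] <- f[a$node, ] - a$ka * (pos[a$node, ] - a$point)
  for (tt in struct$tethers) {
    dv <- pos[tt$node, ] - tt$point
    len_t <- sqrt(sum(dv^2))
    tw <- tether_w(tt, len_t)
    if (tw$dw != 0)
      f[tt$node, ] <- f[tt$node, ] - tw$dw / tt$L0 * dv / len_t
  }
  if (!is.null(struct$walls)) {
    w <- struct$walls
    pen_lo <- pmax(0, (w$y[1] + w$range) - pos[, 2])
    pen_hi <- pmax(0, pos[, 2] - (w$y[2] - w$range))
    f[, 2] <- f[, 2] + w$k * pen_lo - w$k * pen_hi
  }
  if (!is.null(struct$midplane)) {
    m <- struct$midplane
    pen <- pmax(0, m$side * (pos[, 2] - m$y))
    f[, 2] <- f[, 2] - m$k * m$side * pen
  }
  f
}
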