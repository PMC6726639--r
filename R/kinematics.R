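#' Strain invariants of a deformation gradient
#'
#' Computes the first invariant `I1 = tr(C)` and the fiber invariant
#' `I4 = a0 . (C a0)` of the right Cauchy-Green tensor `C = t(F) %*% F`.
#' `I1` measures the overall deformation of the isotropic matrix; `I4` is
#' the squared stretch along the collagen fiber direction `a0`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param a0 unit fiber direction in the reference configuration.
#' @return Named list with elements `I1` and `I4`.
#' @examples
#' invariants(diag(3), c(1, 0, 0))           # I1 = 3, I4 = 1
#' invariants(diag(c(1.2, 1/1.2, 1)), c(1, 0, 0))  # I4 = 1.44
#' @export
invariants <- function(F, a0) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)), length(a0) == 3L)
  if (!all(is.finite(F))) stop("non-finite deformation gradient")
  if (det(F) <= 0) stop("deformation gradient must have det(F) > 0")
  if (abs(sqrt(sum(a0^2)) - 1) > 1e-8) stop("a0 must be a unit vector")
  C <- crossprod(F)                       # t(F) %*% F
  list(I1 = sum(diag(C)), I4 = drop(a0 %*% C %*% a0))
}

new_deformation_state <- function(F, a0) {
  inv <- invariants(F, a0)
  structure(
    list(F = F, a0 = as.numeric(a0), I1 = inv$I1, I4 = inv$I4, J = det(F)),
    class = "deformation_state"
  )
}

#' Biaxial (planar sheet) deformation state
#'
#' Incompressible plane-sheet kinematics for a biaxial stretch test:
#' `F = diag(lambda1, lambda2, 1/(lambda1*lambda2))`, with the collagen
#' fiber direction along axis 1 (the fiber/circumferential test axis) and
#' axis 2 the cross-fiber axis.  The out-of-plane stretch is set by exact
#' incompressibility, so `det(F) = 1` identically.
#'
#' @param lambda1 stretch along the fiber axis (> 0).
#' @param lambda2 stretch along the cross-fiber axis (> 0).
#' @return A `deformation_state`: list with `F`, `a0`, `I1`, `I4`, `J`.
#' @examples
#' s <- biaxial_deformation(1.2, 1.0)
#' s$I4   # 1.44
#' @export
biaxial_deformation <- function(lambda1, lambda2) {
  if (!is.finite(lambda1) || !is.finite(lambda2) || lambda1 <= 0 || lambda2 <= 0)
    stop("stretches must be positive and finite")
  F <- diag(c(lambda1, lambda2, 1 / (lambda1 * lambda2)))
  new_deformation_state(F, c(1, 0, 0))
}

#' Uniaxial deformation state
#'
#' Incompressible uniaxial-tension kinematics used for chordae tensile
#' tests: `F = diag(lambda, 1/sqrt(lambda), 1/sqrt(lambda))`, fiber along
#' axis 1, lateral contraction from exact incompressibility.
#'
#' @param lambda axial stretch (> 0).
#' @return A `deformation_state`.
#' @export
uniaxial_deformation <- function(lambda) {
  if (!is.finite(lambda) || lambda <= 0)
    stop("stretch must be positive and finite")
  F <- diag(c(lambda, 1 / sqrt(lambda), 1 / sqrt(lambda)))
  new_deformation_state(F, c(1, 0, 0))
}

#' @export
print.deformation_state <- function(x, ...) {
  cat("Deformation state (incompressible kinematics)\n")
  cat(sprintf("  I1 = %.6g, I4 = %.6g, J = %.12g\n", x$I1, x$I4, x$J))
  cat("  fiber a0 =", paste(format(x$a0), collapse = " "), "\n")
  invisible(x)
}

#' Stretch protocol for a tensile test
#'
#' Describes a stretch-controlled loading protocol.  Biaxial protocols hold
#' a list of (lambda1, lambda2) paths; uniaxial protocols a single vector
#' of stretches.  Only loading is modelled: all stretches are >= 1 and each
#' path is strictly increasing.
#'
#' @param mode `"biaxial"` or `"uniaxial"`.
#' @param paths for biaxial: a list of two-column matrices/data.frames with
#'   columns `lambda1`, `lambda2`; for uniaxial: a numeric vector of
#'   stretches (or a list of such vectors).
#' @return A `stretch_protocol` object.
#' @export
stretch_protocol <- function(mode = c("biaxial", "uniaxial"), paths) {
  mode <- match.arg(mode)
  if (mode == "uniaxial") {
    if (!is.list(paths)) paths <- list(paths)
    paths <- lapply(paths, function(p) {
      p <- as.numeric(p)
      if (any(p < 1)) stop("protocol stretches must be >= 1 (loading only)")
      if (any(diff(p) <= 0)) stop("protocol paths must be strictly increasing")
      p
    })
  } else {
    if (!is.list(paths) || is.data.frame(paths)) paths <- list(paths)
    paths <- lapply(paths, function(p) {
      p <- as.matrix(as.data.frame(p))
      if (ncol(p) != 2) stop("biaxial paths need columns lambda1, lambda2")
      colnames(p) <- c("lambda1", "lambda2")
      if (any(p < 1)) stop("protocol stretches must be >= 1 (loading only)")
      d <- apply(p, 2, function(v) diff(v))
      if (nrow(p) > 1 && any(apply(as.matrix(d), 1, max) <= 0))
        stop("protocol paths must be strictly increasing in stretch")
      p
    })
  }
  structure(list(mode = mode, paths = paths,
                 n_points = sum(vapply(paths, NROW, 1L))),
            class = "stretch_protocol")
}

#' Default pseudo-biaxial leaflet protocol
#'
#' Three stretch-controlled paths (equibiaxial; fiber-only with
#' `lambda2 = 1`; cross-fiber-only with `lambda1 = 1`) from 1 to
#' `lambda_max`.  The default range 1.0-1.30 spans from the physiological
#' leaflet fiber strains (~0.1) up into the strongly collagen-stiffened
#' regime.
#'
#' @param lambda_max largest stretch per path (default 1.30).
#' @param n_points points per path (default 30).
#' @param paths subset of `c("equibiaxial", "fiber", "cross")`.
#' @return A biaxial `stretch_protocol`.
#' @export
biaxial_protocol <- function(lambda_max = 1.30, n_points = 30,
                             paths = c("equibiaxial", "fiber", "cross")) {
  paths <- match.arg(paths, several.ok = TRUE)
  lam <- seq(1, lambda_max, length.out = n_points)
  built <- list()
  if ("equibiaxial" %in% paths)
    built <- c(built, list(cbind(lambda1 = lam, lambda2 = lam)))
  if ("fiber" %in% paths)
    built <- c(built, list(cbind(lambda1 = lam, lambda2 = rep(1, n_points))))
  if ("cross" %in% paths)
    built <- c(built, list(cbind(lambda1 = rep(1, n_points), lambda2 = lam)))
  stretch_protocol("biaxial", built)
}

#' Default uniaxial chordae protocol
#'
#' Chordae tendineae are stiff; the default range is kept small
#' (stretch 1.0-1.10, 50 points).
#'
#' @param lambda_max largest stretch (default 1.10).
#' @param n_points number of points (default 50).
#' @return A uniaxial `stretch_protocol`.
#' @export
uniaxial_protocol <- function(lambda_max = 1.10, n_points = 50) {
  stretch_protocol("uniaxial", seq(1, lambda_max, length.out = n_points))
}

#' @export
print.stretch_protocol <- function(x, ...) {
  cat(sprintf("Stretch protocol: %s, %d path(s), %d points\n",
              x$mode, length(x$paths), x$n_points))
  invisible(x)
}

# Flatten a protocol to a data.frame of stretch rows.
protocol_rows <- function(protocol) {
  stopifnot(inherits(protocol, "stretch_protocol"))
  if (protocol$mode == "uniaxial") {
    data.frame(lambda = unlist(protocol$paths))
  } else {
    as.data.frame(do.call(rbind, protocol$paths))
  }
}
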