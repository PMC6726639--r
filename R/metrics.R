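# Hemodynamic evaluation metrics computed from solver output.

#' Signed flow rate through a cross-section
#'
#' Integrates the normal (streamwise) velocity over a fixed vertical
#' section of the channel; positive flux is in the inlet-to-outlet
#' (atrium-to-ventricle) direction.  In 2D the flux is per unit depth
#' (cm^2/s); the unit is part of the name to prevent false comparison
#' with 3D mL/s values.
#'
#' @param grid an `eulerian_grid`.
#' @param state grid state with `u`.
#' @param i_section u-face index of the section (1..nx+1).
#' @return Flux in cm^2/s per unit depth.
#' @export
flow_rate <- function(grid, state, i_section) {
  if (i_section < 1 || i_section > grid$nx + 1)
    stop("section outside the domain")
  sum(state$u[i_section, ]) * grid$h
}

#' Closure regurgitation volume from a flow-rate trace
#'
#' Integrates the backward (negative) part of the flow rate over the
#' closure window by the trapezoidal rule:
#' `integral of max(-Q, 0) dt >= 0`.  The default window starts where the
#' driving pressure first reverses sign and runs to the end of the trace.
#'
#' @param trace data.frame with columns `time_s`, a flow-rate column
#'   (first column matching `"flow_rate"`), and optionally `dp_mmHg`.
#' @param window numeric length-2 time window (s), or `NULL` for the
#'   default closure window.
#' @return Regurgitation volume in the trace's flux unit times seconds
#'   (cm^2 per unit depth for 2D traces).
#' @export
regurgitation_volume <- function(trace, window = NULL) {
  qcol <- grep("flow_rate", names(trace), value = TRUE)[1]
  if (is.na(qcol)) stop("trace has no flow-rate column")
  tt <- trace$time_s
  if (is.null(window)) {
    if (!"dp_mmHg" %in% names(trace))
      stop("no dp_mmHg column: supply an explicit closure window")
    rev_idx <- which(trace$dp_mmHg < 0)[1]
    if (is.na(rev_idx)) return(0)
    window <- c(tt[rev_idx], tt[length(tt)])
  }
  if (window[1] < tt[1] - 1e-12 || window[2] > tt[length(tt)] + 1e-12)
    stop("closure window outside the trace")
  keep <- tt >= window[1] & tt <= window[2]
  if (sum(keep) < 2) return(0)
  q <- pmax(-trace[[qcol]][keep], 0)
  x <- tt[keep]
  sum(diff(x) * (q[-1] + q[-length(q)]) / 2)
}

#' Orifice area by free-edge projection
#'
#' Projects a closed free-edge polygon onto the annular plane (given by a
#' point and unit normal) and returns the enclosed area of the projected
#' boundary by the shoelace formula.  Warns (and returns the absolute
#' shoelace value) if the projected polygon self-intersects.
#'
#' @param vertices `n x 3` matrix of free-edge points (cm), ordered along
#'   the closed boundary.
#' @param point a point on the annular plane.
#' @param normal plane normal (need not be unit length).
#' @return Area in cm^2.
#' @export
orifice_area <- function(vertices, point = c(0, 0, 0),
                         normal = c(0, 0, 1)) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3, nrow(vertices) >= 3)
  n <- normal / sqrt(sum(normal^2))
  # orthonormal in-plane basis
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  rel <- sweep(vertices, 2, point)
  xy <- cbind(rel %*% e1, rel %*% e2)
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  area2 <- sum(x * ys - xs * y)
  if (polygon_self_intersects(x, y))
    warning("projected free edge self-intersects; returning absolute ",
            "shoelace area")
  abs(area2) / 2
}

# Brute-force segment-crossing check for small polygons.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) for (j in (i + 2):n) {
    if (i == 1 && j == n) next             # shared vertex with wrap-around
    p <- seg[i, ]; q <- seg[j, ]
    d1 <- cross(p[3] - p[1], p[4] - p[2], q[1] - p[1], q[2] - p[2])
    d2 <- cross(p[3] - p[1], p[4] - p[2], q[3] - p[1], q[4] - p[2])
    d3 <- cross(q[3] - q[1], q[4] - q[2], p[1] - q[1], p[2] - q[2])
    d4 <- cross(q[3] - q[1], q[4] - q[2], p[3] - q[1], p[4] - q[2])
    if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
  }
  FALSE
}

#' Instantaneous valve gap (2D orifice analogue)
#'
#' Tip-to-tip distance between the two leaflet free edges; the 2D
#' stand-in for an orifice area.
#'
#' @param tip_lower,tip_upper length-2 positions, or `n x 2` matrices of
#'   trajectories.
#' @return Distance(s) in cm, always >= 0.
#' @export
gap_opening <- function(tip_lower, tip_upper) {
  a <- rbind(tip_lower); b <- rbind(tip_upper)
  unname(sqrt(rowSums((a - b)^2)))
}

#' Peak velocity magnitude over a field sequence
#'
#' @param fields a single grid state or a list of grid states.
#' @return `max(|u|, |v|)` over all fields (cm/s).
#' @export
peak_velocity <- function(fields) {
  if (!is.null(fields$u)) fields <- list(fields)
  if (length(fields) == 0) stop("empty field sequence")
  max(vapply(fields, function(s) max(abs(s$u), abs(s$v)), numeric(1)))
}
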