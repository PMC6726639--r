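#' Material-law parameter records
#'
#' Constructs a validated parameter record for one of the five hyperelastic
#' laws used for mitral-valve tissue:
#'
#' * `"M1"` — neo-Hookean matrix plus an exponential fiber term:
#'   `Psi = c*(I1 - 3) + a/(2b)*(exp(b*(I4* - 1)^2) - 1)`;
#'   parameters `c` (kPa), `a` (kPa), `b` (dimensionless).
#' * `"M2"` — fully coupled exponential:
#'   `Psi = c0*(exp(c1*(I1 - 3)^2 + c2*(sqrt(I4*) - 1)^4) - 1)`;
#'   `c0` in kPa, `c1`, `c2` treated as dimensionless (see Details).
#' * `"M3"` — fully coupled exponential with a quadratic fiber argument:
#'   `Psi = c0*(exp(c1*(I1 - 3)^2 + c2*(I4* - 1)^2) - 1)`.
#' * `"chordae_linear"` — incompressible neo-Hookean, `Psi = C*(I1 - 3)`,
#'   `C` in kPa.
#' * `"chordae_exp"` — `Psi = a1*(exp(a2*(I1 - 3)) - 1)`, `a1` in kPa,
#'   `a2` dimensionless.
#'
#' `I4* = max(I4, 1)` is the tension-only switch: collagen fibers bear load
#' only when stretched, so the fiber term and its derivative vanish for
#' `I4 <= 1`.
#'
#' @details The exponential constants of M2/M3 multiply powers of
#' dimensionless strain invariants, so they are treated as dimensionless
#' here even though published parameter tables sometimes print kPa against
#' them; only the leading constants `c0` carry stress units.
#'
#' @param law one of `"M1"`, `"M2"`, `"M3"`, `"chordae_linear"`,
#'   `"chordae_exp"`.
#' @param params named numeric vector of non-negative parameters
#'   (names as listed above).
#' @return A `material_law` object.
#' @examples
#' material_law("M1", c(c = 17.43, a = 1.35, b = 5.93))
#' @export
material_law <- function(law, params) {
  if (length(law) != 1 || !law %in% law_ids())
    stop(sprintf("unknown law id '%s'; valid ids: %s",
                 paste(law, collapse = ","),
                 paste(law_ids(), collapse = ", ")))
  need <- law_param_names(law)
  params <- unlist(params)
  if (is.null(names(params)) || !setequal(names(params), need))
    stop(sprintf("law '%s' needs parameters: %s", law,
                 paste(need, collapse = ", ")))
  params <- params[need]
  if (any(!is.finite(params)) || any(params < 0))
    stop("material parameters must be finite and non-negative")
  structure(list(law = law, params = params), class = "material_law")
}

#' Stable law identifiers
#' @return Character vector of the five supported law ids.
#' @export
law_ids <- function() c("M1", "M2", "M3", "chordae_linear", "chordae_exp")

law_param_names <- function(law) {
  switch(law,
    M1 = c("c", "a", "b"),
    M2 = c("c0", "c1", "c2"),
    M3 = c("c0", "c1", "c2"),
    chordae_linear = "C",
    chordae_exp = c("a1", "a2"),
    stop(sprintf("unknown law id '%s'", law))
  )
}

#' Published leaflet parameter presets
#'
#' Parameter records for the M1 leaflet law (anterior: c = 17.43 kPa,
#' a = 1.35 kPa, b = 5.93; posterior: c = 10.25 kPa, a = 0.06 kPa,
#' b = 3.48) and for the M2/M3 laws as fitted per leaflet.
#'
#' @param law `"M1"`, `"M2"` or `"M3"`.
#' @param leaflet `"anterior"` or `"posterior"`.
#' @return A `material_law` object.
#' @export
mv_preset <- function(law = c("M1", "M2", "M3"),
                      leaflet = c("anterior", "posterior")) {
  law <- match.arg(law)
  leaflet <- match.arg(leaflet)
  tab <- list(
    M1 = list(anterior  = c(c = 17.43, a = 1.35, b = 5.93),
              posterior = c(c = 10.25, a = 0.06, b = 3.48)),
    M2 = list(anterior  = c(c0 = 7.69,  c1 = 69.42, c2 = 0.0008),
              posterior = c(c0 = 13.99, c1 = 80.22, c2 = 0.1447)),
    M3 = list(anterior  = c(c0 = 0.29, c1 = 0.47, c2 = 55.39),
              posterior = c(c0 = 0.44, c1 = 2.58, c2 = 61.46))
  )
  material_law(law, tab[[law]][[leaflet]])
}

#' @export
print.material_law <- function(x, ...) {
  cat(sprintf("Material law %s: %s\n", x$law,
              paste(names(x$params), format(x$params), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}

# ---- strain energy ---------------------------------------------------------

#' Strain energy density
#'
#' Evaluates the strain energy `Psi(I1, I4)` (kPa) of a material law at
#' given invariants, with the tension-only switch `I4* = max(I4, 1)`
#' applied to the fiber terms.  `Psi = 0` at the reference state
#' `(I1, I4) = (3, 1)` for every law.
#'
#' @param law a `material_law` object.
#' @param I1,I4 strain invariants (vectorised; `I1 >= 3`, `I4 > 0`).
#' @return Strain energy in kPa.
#' @export
strain_energy <- function(law, I1, I4) {
  stopifnot(inherits(law, "material_law"))
  if (any(I4 <= 0)) stop("I4 must be positive")
  if (any(I1 < 3 - 1e-9)) stop("I1 < 3 is impossible for isochoric deformation")
  p <- law$params
  I4s <- pmax(I4, 1)
  switch(law$law,
    M1 = {
      fib <- if (p[["b"]] > 1e-12)
        p[["a"]] / (2 * p[["b"]]) * (exp(p[["b"]] * (I4s - 1)^2) - 1)
      else p[["a"]] / 2 * (I4s - 1)^2   # b -> 0 limit
      p[["c"]] * (I1 - 3) + fib
    },
    M2 = p[["c0"]] * (exp(p[["c1"]] * (I1 - 3)^2 +
                          p[["c2"]] * (sqrt(I4s) - 1)^4) - 1),
    M3 = p[["c0"]] * (exp(p[["c1"]] * (I1 - 3)^2 +
                          p[["c2"]] * (I4s - 1)^2) - 1),
    chordae_linear = p[["C"]] * (I1 - 3),
    chordae_exp = p[["a1"]] * (exp(p[["a2"]] * (I1 - 3)) - 1)
  )
}

# dPsi/dI1 and dPsi/dI4 with the tension-only switch (fiber derivative is
# identically zero for I4 <= 1).
energy_derivatives <- function(law, I1, I4) {
  p <- law$params
  I4s <- pmax(I4, 1)
  tension <- as.numeric(I4 > 1)
  switch(law$law,
    M1 = list(
      dI1 = rep(p[["c"]], length(I1)),
      dI4 = tension * p[["a"]] * (I4s - 1) * exp(p[["b"]] * (I4s - 1)^2)
    ),
    M2 = {
      Q <- exp(p[["c1"]] * (I1 - 3)^2 + p[["c2"]] * (sqrt(I4s) - 1)^4)
      list(
        dI1 = 2 * p[["c0"]] * p[["c1"]] * (I1 - 3) * Q,
        dI4 = tension * 2 * p[["c0"]] * p[["c2"]] *
          (sqrt(I4s) - 1)^3 / sqrt(I4s) * Q
      )
    },
    M3 = {
      Q <- exp(p[["c1"]] * (I1 - 3)^2 + p[["c2"]] * (I4s - 1)^2)
      list(
        dI1 = 2 * p[["c0"]] * p[["c1"]] * (I1 - 3) * Q,
        dI4 = tension * 2 * p[["c0"]] * p[["c2"]] * (I4s - 1) * Q
      )
    },
    chordae_linear = list(dI1 = rep(p[["C"]], length(I1)),
                          dI4 = rep(0, length(I1))),
    chordae_exp = list(dI1 = p[["a1"]] * p[["a2"]] * exp(p[["a2"]] * (I1 - 3)),
                       dI4 = rep(0, length(I1)))
  )
}

# ---- Cauchy stress ---------------------------------------------------------

#' Cauchy stress of an incompressible hyperelastic law
#'
#' Evaluates `sigma = -lambda_mult * I + 2 F (dPsi/dC) t(F)` for a
#' deformation state with `J = 1`.  The incompressibility multiplier
#' `lambda_mult` (a Lagrange pressure, distinct from the stretches) is
#' eliminated in closed form from the zero-stress condition of the test:
#' plane stress (`sigma33 = 0`) for leaflet sheets, uniaxial
#' (`sigma22 = sigma33 = 0`) for chordae, or supplied directly with
#' `constraint = "none"`.
#'
#' The implemented stresses are the exact derivatives of the strain
#' energies.  Some published closed forms differ from these derivatives
#' (the M1 fiber factor, a missing factor 2 in the linear chordae stress,
#' and a missing `a2` in the exponential chordae stress); those variants
#' are available with `as_printed = TRUE` for comparison only and are not
#' energy-consistent.
#'
#' @param law a `material_law`.
#' @param state a `deformation_state` (must have `J = 1`).
#' @param constraint `"plane_stress"`, `"uniaxial"`, or `"none"`.
#' @param lambda_mult multiplier value (kPa) used when
#'   `constraint = "none"`.
#' @param as_printed use the non-energy-consistent published closed forms.
#' @return A `stress_state`: list with 3x3 `sigma` (kPa) and `lambda_mult`.
#' @examples
#' st <- biaxial_deformation(1.2, 1.2)
#' cauchy_stress(mv_preset("M1", "anterior"), st)$sigma[1, 1]
#' @export
cauchy_stress <- function(law, state,
                          constraint = c("plane_stress", "uniaxial", "none"),
                          lambda_mult = 0, as_printed = FALSE) {
  stopifnot(inherits(law, "material_law"), inherits(state, "deformation_state"))
  constraint <- match.arg(constraint)
  if (abs(state$J - 1) > 1e-8)
    stop("Cauchy stress requires an isochoric state (J = 1)")
  if (state$I4 <= 0) stop("I4 must be positive")

  F <- state$F
  B <- tcrossprod(F)                      # F %*% t(F)
  m <- drop(F %*% state$a0)               # deformed fiber vector
  M <- tcrossprod(m)

  if (!as_printed) {
    d <- energy_derivatives(law, state$I1, state$I4)
    dev <- 2 * d$dI1 * B + 2 * d$dI4 * M
  } else {
    p <- law$params
    I4s <- max(state$I4, 1)
    dev <- switch(law$law,
      M1 = 2 * p[["c"]] * B +
        2 * p[["a"]] * I4s * exp(p[["b"]] * (I4s - 1)^2) * M,
      chordae_linear = p[["C"]] * B,
      chordae_exp = 2 * p[["a1"]] * exp(p[["a2"]] * (state$I1 - 3)) * B,
      {
        d <- energy_derivatives(law, state$I1, state$I4)
        2 * d$dI1 * B + 2 * d$dI4 * M    # M2/M3 print the derivative form
      }
    )
  }

  lam <- switch(constraint,
    plane_stress = dev[3, 3],
    uniaxial = dev[3, 3],
    none = lambda_mult
  )
  sigma <- dev - lam * diag(3)
  if (constraint == "uniaxial" && abs(sigma[2, 2]) >
        1e-8 * max(1, max(abs(sigma))))
    stop("uniaxial constraint inconsistent with deformation state")
  structure(list(sigma = sigma, lambda_mult = lam), class = "stress_state")
}

#' @export
print.stress_state <- function(x, ...) {
  cat("Cauchy stress (kPa), lambda_mult =", format(x$lambda_mult), "\n")
  print(signif(x$sigma, 6))
  invisible(x)
}

#' Stress-stretch curve along a protocol
#'
#' Evaluates the Cauchy stress of a law at every point of a stretch
#' protocol: plane-stress biaxial states yield `(sigma11, sigma22)` pairs,
#' uniaxial states a single `sigma11`.
#'
#' @param law a `material_law`.
#' @param protocol a `stretch_protocol`.
#' @param as_printed passed to [cauchy_stress()].
#' @return A `stretch_stress_dataset` (see [stretch_stress_dataset()]).
#' @export
stress_stretch_curve <- function(law, protocol, as_printed = FALSE) {
  stopifnot(inherits(protocol, "stretch_protocol"))
  rows <- protocol_rows(protocol)
  if (protocol$mode == "biaxial") {
    s <- t(mapply(function(l1, l2) {
      sg <- cauchy_stress(law, biaxial_deformation(l1, l2),
                          "plane_stress", as_printed = as_printed)$sigma
      c(sg[1, 1], sg[2, 2])
    }, rows$lambda1, rows$lambda2))
    df <- data.frame(lambda1 = rows$lambda1, lambda2 = rows$lambda2,
                     sigma11_kPa = s[, 1], sigma22_kPa = s[, 2])
  } else {
    s <- vapply(rows$lambda, function(l)
      cauchy_stress(law, uniaxial_deformation(l),
                    "uniaxial", as_printed = as_printed)$sigma[1, 1],
      numeric(1))
    df <- data.frame(lambda = rows$lambda, sigma_kPa = s)
  }
  stretch_stress_dataset(df, mode = protocol$mode, source = "model",
                         law = law$law, params = law$params)
}
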