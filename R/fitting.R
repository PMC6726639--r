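#' Fit configuration
#'
#' Settings for the inverse problem: minimise the summed squared stress
#' residuals subject to lower bounds `c_i > g_i` on the (non-negative)
#' material parameters.  The optimizer is a bounded Levenberg-Marquardt
#' least-squares solver started from `n_starts` log-uniform random points;
#' the exponential laws make the objective non-convex, and multi-start
#' guards against local minima.
#'
#' @param lower scalar lower bound applied to every parameter (kPa or
#'   dimensionless; default 1e-6).
#' @param n_starts number of random starts (default 20).
#' @param seed integer RNG seed controlling the starts.
#' @param tolerance objective convergence tolerance passed to the solver.
#' @param start_range log10 range the random starts are drawn from
#'   (default `c(-2, 3)`, i.e. 0.01 to 1000).
#' @return A `fit_config` list.
#' @export
fit_config <- function(lower = 1e-6, n_starts = 20, seed = 1L,
                       tolerance = 1e-12, start_range = c(-2, 3)) {
  stopifnot(lower >= 0, n_starts >= 1, length(start_range) == 2)
  structure(list(lower = lower, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), tolerance = tolerance,
                 start_range = start_range),
            class = "fit_config")
}

# Model stresses for every dataset row; returns a matrix with one column
# per fitted stress component (sigma11[, sigma22] or sigma).
model_stresses <- function(law, dataset) {
  md <- attr(dataset, "metadata")
  if (md$mode == "biaxial") {
    s <- t(mapply(function(l1, l2) {
      sg <- cauchy_stress(law, biaxial_deformation(l1, l2),
                          "plane_stress")$sigma
      c(sg[1, 1], sg[2, 2])
    }, dataset$lambda1, dataset$lambda2))
    colnames(s) <- c("sigma11_kPa", "sigma22_kPa")
    s
  } else {
    s <- vapply(dataset$lambda, function(l)
      cauchy_stress(law, uniaxial_deformation(l), "uniaxial")$sigma[1, 1],
      numeric(1))
    matrix(s, ncol = 1, dimnames = list(NULL, "sigma_kPa"))
  }
}

observed_stresses <- function(dataset) {
  md <- attr(dataset, "metadata")
  if (md$mode == "biaxial")
    as.matrix(dataset[c("sigma11_kPa", "sigma22_kPa")])
  else as.matrix(dataset["sigma_kPa"])
}

stress_residuals <- function(params, law_id, dataset) {
  law <- material_law(law_id, params)
  r <- as.numeric(model_stresses(law, dataset) - observed_stresses(dataset))
  r[!is.finite(r)] <- 1e10   # steer the optimizer away from exp() overflow
  r
}

#' Least-squares fitting objective
#'
#' The summed squared Cauchy-stress residual over a dataset,
#' `sum((sigma11_model - sigma11_exp)^2 + (sigma22_model - sigma22_exp)^2)`
#' for biaxial data (the second term is absent for uniaxial data).
#'
#' @param params named parameter vector for `law_id`.
#' @param law_id law identifier (see [law_ids()]).
#' @param dataset a `stretch_stress_dataset`.
#' @return Objective value in kPa^2.
#' @export
objective <- function(params, law_id, dataset) {
  sum(stress_residuals(params, law_id, dataset)^2)
}

#' Generate noiseless pseudo-experimental data from a reference law
#'
#' Evaluates a reference law (by default the M1 anterior parameter preset)
#' over a stretch protocol to produce the "pseudo" biaxial dataset used to
#' calibrate the other leaflet laws against M1.
#'
#' @param law a `material_law` (default `mv_preset("M1", "anterior")`).
#' @param protocol a `stretch_protocol` (default [biaxial_protocol()]).
#' @return A noiseless `stretch_stress_dataset` with source `"pseudo"`.
#' @export
generate_pseudo_data <- function(law = mv_preset("M1", "anterior"),
                                 protocol = biaxial_protocol()) {
  ds <- stress_stretch_curve(law, protocol)
  md <- attr(ds, "metadata")
  md$source <- "pseudo"
  attr(ds, "metadata") <- md
  ds
}

#' Coefficient of determination per stress component
#'
#' `R^2 = 1 - SSE/SST` computed independently for each fitted stress
#' component, where SSE is the residual sum of squares and SST the total
#' sum of squares about the observed mean.  Can be negative for bad fits.
#'
#' @param dataset a `stretch_stress_dataset`.
#' @param predictions matrix/data.frame of model stresses with the same
#'   shape as the observed stress columns.
#' @return Named vector: `fiber` (sigma11) and, for biaxial data,
#'   `crossfiber` (sigma22).
#' @export
r_squared <- function(dataset, predictions) {
  obs <- observed_stresses(dataset)
  pred <- as.matrix(predictions)
  if (!all(dim(pred) == dim(obs)))
    stop("predictions must match the observed stress columns")
  if (nrow(obs) < 2) stop("R-squared needs at least two observations")
  r2 <- vapply(seq_len(ncol(obs)), function(j) {
    sst <- sum((obs[, j] - mean(obs[, j]))^2)
    if (sst == 0) stop("R-squared undefined: constant observations (SST = 0)")
    1 - sum((obs[, j] - pred[, j])^2) / sst
  }, numeric(1))
  names(r2) <- if (ncol(obs) == 2) c("fiber", "crossfiber") else "fiber"
  r2
}

#' Mean absolute stress residual
#'
#' The "average error" reported alongside fits: the mean absolute residual
#' (kPa) across all fitted stress components.  This is a declared
#' interpretation of a conventional summary column whose published
#' definition is unstated; it is reported for orientation and never used
#' as a pass/fail criterion.
#'
#' @inheritParams r_squared
#' @return Mean absolute residual in kPa.
#' @export
average_error <- function(dataset, predictions) {
  obs <- observed_stresses(dataset)
  pred <- as.matrix(predictions)
  if (!all(dim(pred) == dim(obs)))
    stop("predictions must match the observed stress columns")
  mean(abs(obs - pred))
}

#' Fit a constitutive law to stretch-stress data
#'
#' Solves the bounded least-squares inverse problem with a seeded
#' multi-start Levenberg-Marquardt solver ([minpack.lm::nls.lm]) and
#' returns the best solution across starts with goodness-of-fit
#' diagnostics.  Deterministic given `(dataset, config$seed)`.
#'
#' @param law_id law identifier (see [law_ids()]).
#' @param dataset a `stretch_stress_dataset`.
#' @param config a [fit_config()].
#' @return A `fit_result`: estimated parameters, objective (kPa^2),
#'   per-component R-squared, average error (kPa), number of converged
#'   starts and the index of the best start.
#' @examples
#' ds <- generate_pseudo_data(mv_preset("M1", "anterior"),
#'                            biaxial_protocol(n_points = 10))
#' fit_law("M1", ds, fit_config(n_starts = 5, seed = 42))
#' @export
fit_law <- function(law_id, dataset, config = fit_config()) {
  law_id <- match.arg(law_id, law_ids())
  stopifnot(inherits(dataset, "stretch_stress_dataset"),
            inherits(config, "fit_config"))
  pnames <- law_param_names(law_id)
  npar <- length(pnames)
  ncomp <- ncol(observed_stresses(dataset))
  if (nrow(dataset) * ncomp < npar)
    stop("degenerate fitting problem: fewer observations than parameters")

  starts <- local_seed(config$seed, {
    matrix(10^stats::runif(config$n_starts * npar,
                           config$start_range[1], config$start_range[2]),
           nrow = config$n_starts)
  })

  best <- NULL
  best_obj <- Inf
  best_start <- NA_integer_
  n_conv <- 0L
  ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = config$tolerance,
                                     ptol = 1e-12)
  for (k in seq_len(config$n_starts)) {
    p0 <- pmax(starts[k, ], config$lower)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = stats::setNames(p0, pnames),
                         lower = rep(config$lower, npar),
                         fn = stress_residuals, law_id = law_id,
                         dataset = dataset, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(fit$fvec^2)
    if (is.finite(obj)) {
      n_conv <- n_conv + 1L
      if (obj < best_obj) {
        best <- fit
        best_obj <- obj
        best_start <- k
      }
    }
  }
  if (is.null(best))
    stop("all optimizer starts failed to converge; ",
         "check the dataset and bounds")

  params <- stats::setNames(pmax(best$par, config$lower), pnames)
  law <- material_law(law_id, params)
  pred <- model_stresses(law, dataset)
  structure(list(
    law = law_id,
    params = params,
    objective = best_obj,
    r_squared = r_squared(dataset, pred),
    average_error = average_error(dataset, pred),
    n_starts_converged = n_conv,
    best_start = best_start,
    predictions = pred,
    config = config
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of law %s (%d/%d starts converged, best start %d)\n",
              x$law, x$n_starts_converged, x$config$n_starts, x$best_start))
  cat("  parameters:",
      paste(names(x$params), signif(x$params, 6), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  objective = %.6g kPa^2, average error = %.4g kPa\n",
              x$objective, x$average_error))
  cat("  R-squared:",
      paste(names(x$r_squared), round(x$r_squared, 4), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

# Run code under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
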