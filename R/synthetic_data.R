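#' Synthetic tensile-experiment configuration
#'
#' Describes an emulated tensile experiment: planar biaxial stretching for
#' leaflet tissue or uniaxial stretching for chordae, with a ground-truth
#' constitutive law and a declared noise model.  Stretch is treated as
#' exactly controlled (it is the controlled variable in the rigs being
#' emulated); noise is applied to the measured stresses only.  The
#' generator produces the post-preconditioning loading curve; cyclic
#' preconditioning itself is not simulated.
#'
#' @param tissue `"leaflet_anterior"`, `"leaflet_posterior"` or
#'   `"chordae"`.
#' @param truth_law a `material_law` used as ground truth.  Defaults: M1
#'   with the published per-leaflet parameters for leaflet tissue, the
#'   exponential chordae law with a1 = 10 kPa, a2 = 30 for chordae
#'   (MPa-scale stresses at stretch 1.1, typical of chordae).
#' @param protocol a `stretch_protocol`; defaults to [biaxial_protocol()]
#'   for leaflets and [uniaxial_protocol()] for chordae.
#' @param noise `"none"`, `"additive_gaussian"` (sd `sigma_noise` kPa) or
#'   `"proportional_gaussian"` (coefficient of variation `cv`).
#' @param sigma_noise additive noise sd in kPa (>= 0).
#' @param cv proportional noise coefficient of variation (>= 0).
#' @param seed integer RNG seed, recorded in the output metadata.
#' @param n_replicates number of noisy replicates to generate.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(tissue = c("leaflet_anterior",
                                         "leaflet_posterior", "chordae"),
                              truth_law = NULL, protocol = NULL,
                              noise = c("none", "additive_gaussian",
                                        "proportional_gaussian"),
                              sigma_noise = 0, cv = 0, seed = 1L,
                              n_replicates = 1L) {
  tissue <- match.arg(tissue)
  noise <- match.arg(noise)
  stopifnot(sigma_noise >= 0, cv >= 0, n_replicates >= 1)
  if (is.null(truth_law)) {
    truth_law <- switch(tissue,
      leaflet_anterior  = mv_preset("M1", "anterior"),
      leaflet_posterior = mv_preset("M1", "posterior"),
      chordae = material_law("chordae_exp", c(a1 = 10, a2 = 30)))
  }
  stopifnot(inherits(truth_law, "material_law"))
  leaflet_laws <- c("M1", "M2", "M3")
  if (tissue != "chordae" && !(truth_law$law %in% leaflet_laws))
    stop("leaflet tissue requires a leaflet law (M1/M2/M3)")
  if (tissue == "chordae" &&
      !(truth_law$law %in% c("chordae_linear", "chordae_exp")))
    stop("chordae tissue requires a chordae law")
  if (is.null(protocol)) {
    protocol <- if (tissue == "chordae") uniaxial_protocol()
                else biaxial_protocol()
  }
  expected_mode <- if (tissue == "chordae") "uniaxial" else "biaxial"
  if (protocol$mode != expected_mode)
    stop(sprintf("tissue '%s' requires a %s protocol", tissue, expected_mode))
  structure(list(tissue = tissue, truth_law = truth_law, protocol = protocol,
                 noise = noise, sigma_noise = sigma_noise, cv = cv,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "experiment_config")
}

apply_noise <- function(values, config) {
  switch(config$noise,
    none = values,
    additive_gaussian = values +
      stats::rnorm(length(values), 0, config$sigma_noise),
    proportional_gaussian = if (config$cv == 0) values else
      values * (1 + stats::rnorm(length(values), 0, config$cv))
  )
}

generate_experiment <- function(config) {
  clean <- stress_stretch_curve(config$truth_law, config$protocol)
  scol <- if (dataset_mode(clean) == "biaxial")
    c("sigma11_kPa", "sigma22_kPa") else "sigma_kPa"
  reps <- local_seed(config$seed, {
    lapply(seq_len(config$n_replicates), function(r) {
      df <- as.data.frame(clean)
      df[scol] <- apply_noise(as.matrix(df[scol]), config)
      df$replicate <- r
      df
    })
  })
  out <- do.call(rbind, reps)
  rep_col <- out$replicate
  out$replicate <- NULL
  ds <- stretch_stress_dataset(out, mode = dataset_mode(clean),
                               source = "synthetic",
                               specimen = config$tissue,
                               law = config$truth_law$law,
                               params = config$truth_law$params,
                               seed = config$seed)
  ds$replicate <- rep_col
  ds
}

#' Generate a synthetic leaflet biaxial experiment
#'
#' Emulates a planar biaxial tensile test on leaflet tissue: evaluates the
#' ground-truth law over the protocol and applies the configured stress
#' noise.  With `noise = "none"` the output equals the constitutive
#' stress-stretch curve exactly.
#'
#' @param config an [experiment_config()] with a leaflet tissue.
#' @return A `stretch_stress_dataset` (with a `replicate` column when
#'   `n_replicates > 1`).
#' @export
generate_leaflet_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$tissue == "chordae")
    stop("config describes a chordae experiment; use ",
         "generate_chordae_experiment()")
  generate_experiment(config)
}

#' Generate a synthetic chordae uniaxial experiment
#'
#' Emulates a uniaxial tensile test on a chorda: ground-truth law over a
#' uniaxial protocol plus the configured stress noise.
#'
#' @param config an [experiment_config()] with `tissue = "chordae"`.
#' @return A `stretch_stress_dataset`.
#' @export
generate_chordae_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$tissue != "chordae")
    stop("config describes a leaflet experiment; use ",
         "generate_leaflet_experiment()")
  generate_experiment(config)
}

#' Default linear-chordae ground truth
#'
#' Neo-Hookean chordae material with C = 2000 kPa, chosen so that uniaxial
#' stress at stretch 1.1 is ~1.2 MPa, the stiffness scale of porcine
#' chordae.
#' @return A `material_law`.
#' @export
chordae_linear_default <- function() material_law("chordae_linear",
                                                  c(C = 2000))
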