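#' Stretch-stress dataset
#'
#' The fitting currency of the package: a data.frame of stretch-controlled
#' observations with Cauchy stresses in kPa, plus metadata.  Biaxial
#' datasets have columns `lambda1, lambda2, sigma11_kPa, sigma22_kPa`;
#' uniaxial datasets `lambda, sigma_kPa`.
#'
#' @param df data.frame with the columns above; stretches >= 1, finite
#'   stresses, at least one row.
#' @param mode `"biaxial"` or `"uniaxial"`.
#' @param source provenance tag, e.g. `"model"`, `"synthetic"`, `"file"`.
#' @param specimen free-text specimen label.
#' @param law,params optional generating law id and parameters.
#' @param seed optional RNG seed used to generate the data.
#' @return A data.frame of class `stretch_stress_dataset` with a
#'   `metadata` attribute.
#' @export
stretch_stress_dataset <- function(df, mode = c("biaxial", "uniaxial"),
                                   source = "file", specimen = NA_character_,
                                   law = NA_character_, params = NULL,
                                   seed = NA_integer_) {
  mode <- match.arg(mode)
  need <- if (mode == "biaxial")
    c("lambda1", "lambda2", "sigma11_kPa", "sigma22_kPa")
  else c("lambda", "sigma_kPa")
  if (!all(need %in% names(df)))
    stop(sprintf("%s dataset needs columns: %s", mode,
                 paste(need, collapse = ", ")))
  df <- as.data.frame(df)[need]
  if (nrow(df) < 1) stop("dataset must have at least one row")
  lam_cols <- grep("^lambda", need, value = TRUE)
  if (any(as.matrix(df[lam_cols]) < 1))
    stop("stretches must be >= 1")
  if (any(!is.finite(as.matrix(df))))
    stop("dataset contains non-finite values")
  attr(df, "metadata") <- list(mode = mode, source = source,
                               specimen = specimen, law = law,
                               params = params, seed = seed)
  class(df) <- c("stretch_stress_dataset", "data.frame")
  df
}

#' @export
print.stretch_stress_dataset <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("Stretch-stress dataset: %s, %d rows (source: %s%s)\n",
              md$mode, nrow(x), md$source,
              if (!is.na(md$law)) paste0(", law ", md$law) else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

dataset_mode <- function(dataset) attr(dataset, "metadata")$mode

#' Write / read a stretch-stress dataset
#'
#' Datasets are stored as comma-delimited text (header
#' `lambda1,lambda2,sigma11_kPa,sigma22_kPa`, or `lambda,sigma_kPa` for
#' uniaxial data) with metadata in a YAML sidecar `<path>.meta.yaml`.
#'
#' @param dataset a `stretch_stress_dataset`.
#' @param path file path for the delimited text.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   dataset.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "stretch_stress_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  md <- attr(dataset, "metadata")
  md$params <- as.list(md$params)
  yaml::write_yaml(md, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.yaml")
  md <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  mode <- md$mode %||% if ("lambda1" %in% names(df)) "biaxial" else "uniaxial"
  stretch_stress_dataset(df, mode = mode,
                         source = md$source %||% "file",
                         specimen = md$specimen %||% NA_character_,
                         law = md$law %||% NA_character_,
                         params = unlist(md$params),
                         seed = md$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
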