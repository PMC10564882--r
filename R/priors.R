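#' Prior configuration for the hierarchical ordered-probit model
#'
#' Bundles the three prior families the model needs: a location-scale
#' prior shared by the regression coefficients (condition effect, CIA main
#' effect, interaction), a positive-support prior for the random-slope SD,
#' and a location-scale prior applied to each cutpoint jointly with the
#' structural ordering constraint. Defaults are weakly informative:
#' normal(0, 2.5) on coefficients, half-Cauchy(0, 2.5) on the SD, and a
#' heavy-tailed Student-t(3, 0, 2.5) on cutpoints.
#'
#' @param coef_family `"normal"` or `"student_t"`.
#' @param coef_location,coef_scale Location and scale of the coefficient
#'   prior (scale > 0).
#' @param coef_df Degrees of freedom when `coef_family = "student_t"`.
#' @param sigma_family One of `"half_cauchy"`, `"half_normal"`,
#'   `"exponential"`, `"half_t"`.
#' @param sigma_scale Scale of the SD prior (> 0); for `"exponential"`
#'   the mean, i.e. rate `1/sigma_scale`.
#' @param sigma_df Degrees of freedom when `sigma_family = "half_t"`.
#' @param cutpoint_family `"student_t"`, `"normal"` or `"cauchy"`.
#' @param cutpoint_location,cutpoint_scale Location and scale of the
#'   per-cutpoint prior (scale > 0).
#' @param cutpoint_df Degrees of freedom when
#'   `cutpoint_family = "student_t"`.
#' @return An object of class `rhi_prior`.
#' @export
prior_config <- function(coef_family = c("normal", "student_t"),
                         coef_location = 0, coef_scale = 2.5, coef_df = 3,
                         sigma_family = c("half_cauchy", "half_normal",
                                          "exponential", "half_t"),
                         sigma_scale = 2.5, sigma_df = 3,
                         cutpoint_family = c("student_t", "normal", "cauchy"),
                         cutpoint_location = 0, cutpoint_scale = 2.5,
                         cutpoint_df = 3) {
  coef_family <- match.arg(coef_family)
  sigma_family <- match.arg(sigma_family)
  cutpoint_family <- match.arg(cutpoint_family)
  stopifnot(coef_scale > 0, sigma_scale > 0, cutpoint_scale > 0)
  structure(
    list(coef = list(family = coef_family, location = coef_location,
                     scale = coef_scale, df = coef_df),
         sigma = list(family = sigma_family, scale = sigma_scale,
                      df = sigma_df),
         cutpoint = list(family = cutpoint_family,
                         location = cutpoint_location,
                         scale = cutpoint_scale, df = cutpoint_df)),
    class = "rhi_prior"
  )
}

#' @export
print.rhi_prior <- function(x, ...) {
  cat("<rhi_prior>\n")
  cat("  coefficients: ", x$coef$family, "(", x$coef$location, ", ",
      x$coef$scale, ")\n", sep = "")
  cat("  sigma_r:      ", x$sigma$family, "(scale ", x$sigma$scale, ")\n",
      sep = "")
  cat("  cutpoints:    ", x$cutpoint$family, "(", x$cutpoint$location,
      ", ", x$cutpoint$scale, ")\n", sep = "")
  invisible(x)
}

#' Read a prior configuration from YAML or JSON
#'
#' The file holds any subset of the arguments of [prior_config()] as
#' top-level keys (e.g. `sigma_family: half_normal`); unspecified fields
#' keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `rhi_prior`.
#' @export
read_prior_config <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(prior_config))
  unknown <- setdiff(names(spec), known)
  if (length(unknown) > 0L) {
    stop("unknown prior configuration key(s): ",
         paste(unknown, collapse = ", "))
  }
  do.call(prior_config, spec)
}

# Log density of a location-scale prior at x (vectorized).
ls_log_density <- function(x, family, location, scale, df) {
  switch(family,
    normal = stats::dnorm(x, location, scale, log = TRUE),
    student_t = stats::dt((x - location) / scale, df = df, log = TRUE) -
      log(scale),
    cauchy = stats::dcauchy(x, location, scale, log = TRUE),
    stop("unknown location-scale family: ", family)
  )
}

# Log density of a positive-support prior at sigma > 0.
sigma_log_density <- function(sigma, family, scale, df) {
  switch(family,
    half_cauchy = log(2) + stats::dcauchy(sigma, 0, scale, log = TRUE),
    half_normal = log(2) + stats::dnorm(sigma, 0, scale, log = TRUE),
    exponential = stats::dexp(sigma, rate = 1 / scale, log = TRUE),
    half_t = log(2) + stats::dt(sigma / scale, df = df, log = TRUE) -
      log(scale),
    stop("unknown sigma prior family: ", family)
  )
}
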