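## Common fit container and OLS helpers shared by the isotherm and kinetic
## fitters. All linearized fits run through stats::lm; parameter standard
## deviations are propagated from the slope/intercept covariance by the
## first-order delta method.

#' Construct a model fit record
#'
#' Container returned by every isotherm/kinetic fitter: named parameters
#' with matching standard deviations, the coefficient of determination in
#' the space the regression was performed in, and a validity flag for
#' non-physical fits (e.g. a negative Langmuir slope) so comparisons can
#' still rank them instead of aborting.
#'
#' @param model_name one of `"freundlich"`, `"langmuir"`, `"temkin"`,
#'   `"pseudo_first"`, `"pseudo_second"`, `"intraparticle"`,
#'   `"fractional_power"`, `"elovich"`.
#' @param parameters named numeric vector of fitted parameters.
#' @param parameter_sd named numeric vector of standard deviations; names
#'   must equal those of `parameters`.
#' @param r_squared coefficient of determination (<= 1).
#' @param fit_mode `"linearized"` or `"nonlinear"`.
#' @param valid FALSE when the fit is flagged non-physical.
#' @param units named character vector of parameter units (metadata only).
#' @param details free-form list (segments, breakpoints, notes, predictors).
#' @return An object of class `adsorb_fit`.
#' @export
model_fit <- function(model_name, parameters, parameter_sd, r_squared,
                      fit_mode = c("linearized", "nonlinear"),
                      valid = TRUE, units = NULL, details = list()) {
  model_name <- match.arg(model_name, c(
    "freundlich", "langmuir", "temkin", "pseudo_first", "pseudo_second",
    "intraparticle", "fractional_power", "elovich"))
  fit_mode <- match.arg(fit_mode)
  if (!setequal(names(parameters), names(parameter_sd)))
    stop("parameter_sd names must match parameters names")
  parameter_sd <- parameter_sd[names(parameters)]
  if (is.finite(r_squared) && r_squared > 1 + 1e-12)
    stop("r_squared cannot exceed 1")
  structure(
    list(model_name = model_name,
         parameters = parameters,
         parameter_sd = parameter_sd,
         r_squared = r_squared,
         fit_mode = fit_mode,
         valid = isTRUE(valid),
         units = units,
         details = details),
    class = "adsorb_fit"
  )
}

#' @export
print.adsorb_fit <- function(x, ...) {
  cat(sprintf("<%s fit, %s mode>%s\n", x$model_name, x$fit_mode,
              if (x$valid) "" else "  [flagged non-physical]"))
  for (nm in names(x$parameters)) {
    u <- if (!is.null(x$units) && nm %in% names(x$units)) x$units[[nm]] else ""
    cat(sprintf("  %-12s %.6g +/- %.3g %s\n", nm, x$parameters[[nm]],
                x$parameter_sd[[nm]], u))
  }
  cat(sprintf("  R^2 = %.6f\n", x$r_squared))
  if (length(x$details$notes))
    cat("  note:", paste(x$details$notes, collapse = "; "), "\n")
  invisible(x)
}

## Simple-OLS workhorse: returns slope/intercept, their covariance, and R^2
## computed in the regression space.
.ols <- function(x, y) {
  if (length(x) < 2) stop("need at least 2 points for a line")
  fit <- lm(y ~ x)
  cf <- coef(fit)
  n <- length(x)
  ybar <- mean(y)
  sst <- sum((y - ybar)^2)
  sse <- sum(residuals(fit)^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  # suppress the "essentially perfect fit" warning: exact model-generated
  # fixtures are a routine input here
  vc <- if (n > 2) suppressWarnings(vcov(fit)) else matrix(0, 2, 2)
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       se_intercept = sqrt(vc[1, 1]), se_slope = sqrt(vc[2, 2]),
       cov = vc, r_squared = r2, sse = sse, fit = fit)
}

## Delta-method SD of g(intercept, slope) given gradient and 2x2 covariance.
.delta_sd <- function(grad, cov) {
  v <- drop(t(grad) %*% cov %*% grad)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

## R^2 in response space for nonlinear fits.
.r2_response <- function(obs, fitted) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(1)
  1 - sum((obs - fitted)^2) / sst
}
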