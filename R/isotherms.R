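## Equilibrium isotherm fitters. Each model is fit either through the
## classical linearization (the convention the tabulated literature values
## follow, and this package's default) or by direct nonlinear least squares
## on the isotherm curve, initialized from the linearized estimate.
##
## Linearizations:
##   Freundlich  qe = kF Ce^(1/n)          ->  ln qe   = ln kF + (1/n) ln Ce
##   Langmuir    qe = qmax KL Ce/(1+KL Ce) ->  Ce/qe   = Ce/qmax + 1/(qmax KL)
##   Temkin      qe = (RT/b) ln(kT Ce)     ->  qe      = (RT/b) ln kT + (RT/b) ln Ce
##
## R^2 is reported in the space the regression ran in (linearized space for
## linearized mode), matching how the literature tabulates it.

.iso_check <- function(data) {
  stopifnot(inherits(data, "isotherm_dataset"))
  if (any(data$qe <= 0)) {
    bad <- which(data$qe <= 0)[1]
    stop("qe must be positive for isotherm fitting; row ", bad,
         " has qe = ", data$qe[bad])
  }
}

#' Fit the Freundlich isotherm
#'
#' Heterogeneous-surface model `qe = kF * Ce^(1/n)`. Linearized mode
#' regresses ln(qe) on ln(Ce): slope = 1/n, intercept = ln(kF). Nonlinear
#' mode refits the direct form by Levenberg-Marquardt least squares starting
#' from the linearized estimate.
#'
#' @param data an [isotherm_dataset()] with strictly positive Ce and qe.
#' @param mode `"linearized"` (default) or `"nonlinear"`.
#' @return An `adsorb_fit` with parameters `kF` (mg g-1) and `inv_n`
#'   (dimensionless adsorption-intensity exponent 1/n).
#' @export
fit_freundlich <- function(data, mode = c("linearized", "nonlinear")) {
  mode <- match.arg(mode)
  .iso_check(data)
  ols <- .ols(log(data$Ce), log(data$qe))
  kF <- exp(ols$intercept)
  inv_n <- ols$slope
  sd_kF <- kF * ols$se_intercept           # d(exp(i))/di = exp(i)
  sd_inv_n <- ols$se_slope
  fit <- model_fit(
    "freundlich",
    parameters = c(kF = kF, inv_n = inv_n),
    parameter_sd = c(kF = sd_kF, inv_n = sd_inv_n),
    r_squared = ols$r_squared,
    fit_mode = "linearized",
    units = c(kF = "mg g-1", inv_n = ""),
    details = list(linear_form = "ln(qe) ~ ln(Ce)")
  )
  if (mode == "linearized") return(fit)
  .nls_refit(fit, data, function(p, ce) p[["kF"]] * ce^p[["inv_n"]],
             lower = c(kF = 1e-12, inv_n = -Inf))
}

#' Fit the Langmuir isotherm
#'
#' Monolayer-site model `qe = qmax * KL * Ce / (1 + KL * Ce)`. Linearized
#' mode regresses Ce/qe on Ce: slope = 1/qmax, intercept = 1/(qmax*KL). A
#' non-positive slope leaves qmax undefined; the fit is then returned with
#' `valid = FALSE` rather than raising, so model comparisons can still rank
#' it (this is exactly the situation where the Langmuir model is rejected
#' for strongly heterogeneous adsorbents).
#'
#' @inheritParams fit_freundlich
#' @return An `adsorb_fit` with parameters `qmax` (mg g-1) and `KL`
#'   (mL mg-1, per the Ce/qe linearization).
#' @export
fit_langmuir <- function(data, mode = c("linearized", "nonlinear")) {
  mode <- match.arg(mode)
  .iso_check(data)
  ols <- .ols(data$Ce, data$Ce / data$qe)
  s <- ols$slope; i <- ols$intercept
  valid <- s > 0
  notes <- character()
  qmax <- if (valid) 1 / s else NA_real_
  KL <- if (valid && i != 0) s / i else if (valid) Inf else NA_real_
  if (valid && i <= 0) notes <- c(notes,
    "non-positive intercept: KL unbounded (saturated or noise-dominated data)")
  if (!valid) notes <- c(notes, "non-positive slope: qmax undefined")
  sd_qmax <- if (valid) ols$se_slope / s^2 else NA_real_   # d(1/s)/ds = -1/s^2
  sd_KL <- if (valid && i > 0)
    .delta_sd(c(-s / i^2, 1 / i), ols$cov) else NA_real_   # KL = s/i
  fit <- model_fit(
    "langmuir",
    parameters = c(qmax = qmax, KL = KL),
    parameter_sd = c(qmax = sd_qmax, KL = sd_KL),
    r_squared = ols$r_squared,
    fit_mode = "linearized",
    valid = valid,
    units = c(qmax = "mg g-1", KL = "mL mg-1"),
    details = list(linear_form = "Ce/qe ~ Ce", notes = notes)
  )
  if (mode == "linearized" || !valid) return(fit)
  .nls_refit(fit, data,
             function(p, ce) p[["qmax"]] * p[["KL"]] * ce / (1 + p[["KL"]] * ce),
             lower = c(qmax = 1e-12, KL = 1e-12))
}

#' Fit the Temkin isotherm
#'
#' Adsorbate-interaction model `qe = (RT/b) ln(kT * Ce)`, linear in ln(Ce):
#' slope = RT/b, intercept = (RT/b) ln(kT). The Temkin constant `b`
#' (kJ mol-1) is tied to the heat of sorption via `deltaH = -b`, reported in
#' the fit details; a negative slope (capacity falling with concentration)
#' is non-physical and flagged.
#'
#' @inheritParams fit_freundlich
#' @param temperature_k temperature (K); defaults to the dataset attribute.
#' @return An `adsorb_fit` with parameters `b` (kJ mol-1) and `kT`
#'   (mL g-1), plus `heat_of_sorption` (= -b) in `details`.
#' @export
fit_temkin <- function(data, mode = c("linearized", "nonlinear"),
                       temperature_k = attr(data, "temperature_k")) {
  mode <- match.arg(mode)
  # qe enters untransformed here, so qe = 0 rows are admissible (unlike the
  # log-based Freundlich/Langmuir transforms)
  stopifnot(inherits(data, "isotherm_dataset"))
  stopifnot(is.numeric(temperature_k), temperature_k > 0)
  RT <- R_GAS_KJ * temperature_k
  ols <- .ols(log(data$Ce), data$qe)
  s <- ols$slope; i <- ols$intercept
  valid <- s > 0
  b <- if (valid) RT / s else NA_real_
  kT <- if (valid) exp(i / s) else NA_real_
  sd_b <- if (valid) RT * ols$se_slope / s^2 else NA_real_
  # kT = exp(i/s): grad = kT * (1/s, -i/s^2)
  sd_kT <- if (valid) .delta_sd(kT * c(1 / s, -i / s^2), ols$cov) else NA_real_
  fit <- model_fit(
    "temkin",
    parameters = c(b = b, kT = kT),
    parameter_sd = c(b = sd_b, kT = sd_kT),
    r_squared = ols$r_squared,
    fit_mode = "linearized",
    valid = valid,
    units = c(b = "kJ mol-1", kT = "mL g-1"),
    details = list(linear_form = "qe ~ ln(Ce)",
                   temperature_k = temperature_k,
                   heat_of_sorption = if (valid) -b else NA_real_,
                   notes = if (valid) character() else
                     "non-positive slope: b undefined")
  )
  if (mode == "linearized" || !valid) return(fit)
  .nls_refit(fit, data,
             function(p, ce) (RT / p[["b"]]) * log(p[["kT"]] * ce),
             lower = c(b = 1e-12, kT = 1e-12))
}

## Nonlinear refit shared by all isotherms: Levenberg-Marquardt on the
## direct curve, started at the linearized estimate.
.nls_refit <- function(lin_fit, data, curve, lower) {
  start <- as.list(lin_fit$parameters)
  df <- data.frame(Ce = data$Ce, qe = data$qe)
  names(start) <- c("p1", "p2")
  par_names <- names(lin_fit$parameters)
  nls <- tryCatch(
    minpack.lm::nlsLM(
      qe ~ curve(setNames(c(p1, p2), par_names), Ce),
      data = df, start = start,
      lower = unname(lower[names(lin_fit$parameters)]),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(nls, "error")) {
    lin_fit$details$notes <- c(lin_fit$details$notes,
                               paste("nonlinear refit failed:",
                                     conditionMessage(nls)))
    return(lin_fit)
  }
  est <- coef(nls)
  se <- tryCatch(summary(nls)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  pars <- setNames(unname(est), names(lin_fit$parameters))
  sds <- setNames(unname(se), names(lin_fit$parameters))
  details <- lin_fit$details
  if (lin_fit$model_name == "temkin" && "b" %in% names(pars))
    details$heat_of_sorption <- -pars[["b"]]
  model_fit(
    lin_fit$model_name,
    parameters = pars,
    parameter_sd = sds,
    r_squared = .r2_response(df$qe, fitted(nls)),
    fit_mode = "nonlinear",
    valid = lin_fit$valid,
    units = lin_fit$units,
    details = details
  )
}

#' Fit and rank all three isotherm models
#'
#' Fits Freundlich, Langmuir and Temkin and ranks them by R-squared
#' (computed per `mode`), placing flagged non-physical fits after valid
#' ones; remaining ties are broken by model order (Freundlich, Langmuir,
#' Temkin). A model whose fitter errors contributes a failure record
#' instead of aborting the comparison.
#'
#' @inheritParams fit_freundlich
#' @param temperature_k temperature (K) for the Temkin fit.
#' @return An object of class `isotherm_comparison`: list with `fits`
#'   (named list of `adsorb_fit` or failure records), `ranking` (data.frame,
#'   best first) and `failures`.
#' @export
compare_isotherms <- function(data, mode = c("linearized", "nonlinear"),
                              temperature_k = attr(data, "temperature_k")) {
  mode <- match.arg(mode)
  fitters <- list(
    freundlich = function() fit_freundlich(data, mode),
    langmuir   = function() fit_langmuir(data, mode),
    temkin     = function() fit_temkin(data, mode, temperature_k)
  )
  fits <- list(); failures <- list()
  for (nm in names(fitters)) {
    res <- tryCatch(fitters[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm]] <- conditionMessage(res)
    } else {
      fits[[nm]] <- res
    }
  }
  if (length(fits)) {
    rank_df <- data.frame(
      model = names(fits),
      r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
      valid = vapply(fits, function(f) f$valid, logical(1)),
      order = seq_along(fits),
      stringsAsFactors = FALSE
    )
    rank_df <- rank_df[order(-rank_df$r_squared, !rank_df$valid,
                             rank_df$order), ]
    rank_df$rank <- seq_len(nrow(rank_df))
    rownames(rank_df) <- NULL
    rank_df$order <- NULL
  } else {
    rank_df <- data.frame(model = character(), r_squared = numeric(),
                          valid = logical(), rank = integer())
  }
  structure(list(fits = fits, ranking = rank_df, failures = failures,
                 mode = mode),
            class = "isotherm_comparison")
}

#' @export
print.isotherm_comparison <- function(x, ...) {
  cat(sprintf("Isotherm comparison (%s mode)\n", x$mode))
  print(x$ranking, row.names = FALSE)
  if (length(x$failures)) {
    cat("failed models:\n")
    for (nm in names(x$failures)) cat("  ", nm, ": ", x$failures[[nm]], "\n")
  }
  invisible(x)
}
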