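## Kinetic model fitters. Fitters use the classical printed linearizations;
## the matching integrated forms live in the synthetic-data generators.
##
##   pseudo-first order   log10(qe - qt) = log10(qe) - (k1/ln 10) t
##   pseudo-second order  t/qt = 1/(k2 qe^2) + t/qe
##   intra-particle       qt = ki sqrt(t) + Ci         (piecewise segments)
##   fractional power     ln qt = ln KFP + v ln t
##   Elovich (large-t)    qt = (1/beta) ln(alpha beta) + (1/beta) ln t
##
## t = 0 rows are excluded wherever the transform is undefined (t/qt, ln t).

.kin_check <- function(data) stopifnot(inherits(data, "kinetic_dataset"))

#' Fit the pseudo-first-order (Lagergren) kinetic model
#'
#' Linear regression of log10(qe_exp - qt) on t. The linearization needs the
#' equilibrium capacity before fitting, so the experimentally observed
#' plateau `qe_exp` must be supplied (or carried by the dataset). Points
#' with qt >= qe_exp (where the log is undefined) are excluded with a
#' message reporting how many were dropped.
#'
#' @param data a [kinetic_dataset()].
#' @param qe_exp experimental equilibrium capacity (mg g-1); defaults to the
#'   dataset's `qe_exp` attribute.
#' @return An `adsorb_fit` with parameters `qe` (mg g-1, the fitted
#'   intercept capacity) and `k1` (min-1).
#' @export
fit_pseudo_first <- function(data, qe_exp = attr(data, "qe_exp")) {
  .kin_check(data)
  if (is.null(qe_exp))
    stop("pseudo-first-order linearization requires qe_exp")
  stopifnot(is.numeric(qe_exp), qe_exp > 0)
  usable <- data$qt < qe_exp
  n_dropped <- sum(!usable)
  if (n_dropped > 0)
    message("fit_pseudo_first: excluded ", n_dropped,
            " point(s) with qt >= qe_exp")
  if (sum(usable) < 3)
    stop("fewer than 3 usable points after excluding qt >= qe_exp")
  t <- data$t[usable]
  y <- log10(qe_exp - data$qt[usable])
  ols <- .ols(t, y)
  k1 <- -ols$slope * log(10)
  qe_fit <- 10^ols$intercept
  model_fit(
    "pseudo_first",
    parameters = c(qe = qe_fit, k1 = k1),
    parameter_sd = c(qe = qe_fit * log(10) * ols$se_intercept,
                     k1 = log(10) * ols$se_slope),
    r_squared = ols$r_squared,
    fit_mode = "linearized",
    units = c(qe = "mg g-1", k1 = "min-1"),
    details = list(linear_form = "log10(qe_exp - qt) ~ t",
                   qe_exp = qe_exp, n_excluded = n_dropped)
  )
}

#' Fit the pseudo-second-order (Ho-McKay) kinetic model
#'
#' Linear regression of t/qt on t: slope = 1/qe, intercept = 1/(k2 qe^2).
#' The t = 0 point (t/qt undefined) is excluded. The returned fit carries a
#' closed-form predictor `qt(t) = qe^2 k2 t / (1 + qe k2 t)` in
#' `details$predict`.
#'
#' @param data a [kinetic_dataset()] with qt > 0 at every fitted point.
#' @return An `adsorb_fit` with parameters `qe` (mg g-1) and `k2`
#'   (g mg-1 min-1).
#' @export
fit_pseudo_second <- function(data) {
  .kin_check(data)
  keep <- data$t > 0
  t <- data$t[keep]; qt <- data$qt[keep]
  if (any(qt <= 0)) {
    bad <- which(qt <= 0)[1]
    stop("t/qt is undefined for non-positive qt (t = ", t[bad], " min)")
  }
  if (length(t) < 3) stop("need at least 3 points with t > 0")
  ols <- .ols(t, t / qt)
  s <- ols$slope; i <- ols$intercept
  qe <- 1 / s
  k2 <- s^2 / i
  sd_qe <- ols$se_slope / s^2
  # k2 = s^2/i: grad = (-s^2/i^2, 2s/i)
  sd_k2 <- .delta_sd(c(-s^2 / i^2, 2 * s / i), ols$cov)
  model_fit(
    "pseudo_second",
    parameters = c(qe = qe, k2 = k2),
    parameter_sd = c(qe = sd_qe, k2 = sd_k2),
    r_squared = ols$r_squared,
    fit_mode = "linearized",
    units = c(qe = "mg g-1", k2 = "g mg-1 min-1"),
    details = list(
      linear_form = "t/qt ~ t",
      predict = pseudo_second_qt(qe, k2))
  )
}

#' Pseudo-second-order closed-form capacity curve
#'
#' Returns the integrated-form predictor `qt(t) = qe^2 k2 t / (1 + qe k2 t)`,
#' monotone increasing in t and asymptoting to qe.
#'
#' @param qe equilibrium capacity (mg g-1).
#' @param k2 rate constant (g mg-1 min-1).
#' @return A function of `t` (min) returning qt (mg g-1).
#' @export
pseudo_second_qt <- function(qe, k2) {
  force(qe); force(k2)
  function(t) qe^2 * k2 * t / (1 + qe * k2 * t)
}

#' Fit the Weber-Morris intra-particle diffusion model
#'
#' Piecewise linear regression of qt on sqrt(t). With `n_segments = 2` the
#' breakpoint is chosen by exhaustive search over every admissible split
#' index (each segment keeps at least 3 points) minimizing the total sum of
#' squared errors; SSE ties are broken toward the earlier breakpoint. Each
#' segment reports its rate constant ki (mg g-1 min-1/2), boundary-layer
#' intercept Ci (mg g-1) and segment R-squared. The reported
#' `breakpoint_time` is the intersection time of the two fitted lines
#' (well-defined even when a shared point fits both segments).
#'
#' @param data a [kinetic_dataset()].
#' @param n_segments 1 or 2 diffusion regimes.
#' @return An `adsorb_fit` with parameters `k1`, `C1` (and `k2`, `C2` for
#'   two segments); `details$segments` holds per-segment records and
#'   `details$breakpoint_time` / `details$breakpoint_index` the split.
#' @export
fit_intraparticle <- function(data, n_segments = 2) {
  .kin_check(data)
  stopifnot(n_segments %in% c(1L, 2L))
  t <- data$t; qt <- data$qt
  x <- sqrt(t)
  n <- length(t)
  if (n < 3 * n_segments)
    stop("need at least ", 3 * n_segments, " points for ", n_segments,
         " segment(s); have ", n)
  seg_fit <- function(idx) {
    ols <- .ols(x[idx], qt[idx])
    list(ki = ols$slope, Ci = ols$intercept,
         sd_ki = ols$se_slope, sd_Ci = ols$se_intercept,
         r_squared = ols$r_squared, sse = ols$sse, n = length(idx))
  }
  if (n_segments == 1L) {
    s1 <- seg_fit(seq_len(n))
    return(model_fit(
      "intraparticle",
      parameters = c(k1 = s1$ki, C1 = s1$Ci),
      parameter_sd = c(k1 = s1$sd_ki, C1 = s1$sd_Ci),
      r_squared = s1$r_squared,
      fit_mode = "linearized",
      units = c(k1 = "mg g-1 min-1/2", C1 = "mg g-1"),
      details = list(segments = list(s1), n_segments = 1L)
    ))
  }
  splits <- 3:(n - 3)                     # last index of segment 1
  best <- NULL; best_sse <- Inf; best_i <- NA_integer_
  for (i in splits) {
    s1 <- seg_fit(1:i); s2 <- seg_fit((i + 1):n)
    sse <- s1$sse + s2$sse
    if (sse < best_sse) {                  # strict <: ties keep earlier split
      best_sse <- sse; best <- list(s1, s2); best_i <- i
    }
  }
  s1 <- best[[1]]; s2 <- best[[2]]
  # Breakpoint = intersection of the two fitted lines in sqrt(t).
  bp_time <- if (s1$ki != s2$ki) {
    ((s2$Ci - s1$Ci) / (s1$ki - s2$ki))^2
  } else {
    mean(c(t[best_i], t[best_i + 1]))     # parallel lines: midpoint of split
  }
  model_fit(
    "intraparticle",
    parameters = c(k1 = s1$ki, C1 = s1$Ci, k2 = s2$ki, C2 = s2$Ci),
    parameter_sd = c(k1 = s1$sd_ki, C1 = s1$sd_Ci,
                     k2 = s2$sd_ki, C2 = s2$sd_Ci),
    r_squared = 1 - best_sse / max(sum((qt - mean(qt))^2), .Machine$double.eps),
    fit_mode = "linearized",
    units = c(k1 = "mg g-1 min-1/2", C1 = "mg g-1",
              k2 = "mg g-1 min-1/2", C2 = "mg g-1"),
    details = list(segments = best, n_segments = 2L,
                   breakpoint_index = best_i,
                   breakpoint_time = bp_time,
                   total_sse = best_sse)
  )
}

#' Fit the fractional power kinetic model
#'
#' Linear regression of ln(qt) on ln(t): slope = v, intercept = ln(KFP).
#' Points with t = 0 or qt = 0 are excluded. An exponent v < 1 is the
#' model's usual validity signature and is noted in the fit details.
#'
#' @param data a [kinetic_dataset()].
#' @return An `adsorb_fit` with parameters `KFP` and `v`.
#' @export
fit_fractional_power <- function(data) {
  .kin_check(data)
  keep <- data$t > 0 & data$qt > 0
  if (sum(keep) < 3) stop("need at least 3 points with t > 0 and qt > 0")
  ols <- .ols(log(data$t[keep]), log(data$qt[keep]))
  KFP <- exp(ols$intercept)
  v <- ols$slope
  model_fit(
    "fractional_power",
    parameters = c(KFP = KFP, v = v),
    parameter_sd = c(KFP = KFP * ols$se_intercept, v = ols$se_slope),
    r_squared = ols$r_squared,
    fit_mode = "linearized",
    units = c(KFP = "mg g-1 min-v", v = ""),
    details = list(linear_form = "ln(qt) ~ ln(t)",
                   v_below_unity = v < 1)
  )
}

#' Fit the Elovich kinetic model
#'
#' Linear regression of qt on ln(t) using the large-t simplified Elovich
#' form `qt = (1/beta) ln(alpha beta) + (1/beta) ln(t)`: slope = 1/beta,
#' intercept = (1/beta) ln(alpha beta). The chemisorption-rate constant
#' alpha and surface-coverage constant beta are recovered from slope and
#' intercept; beta is positive whenever qt increases with ln(t).
#'
#' @param data a [kinetic_dataset()].
#' @return An `adsorb_fit` with parameters `alpha` (mg g-1 min-1) and
#'   `beta` (g mg-1).
#' @export
fit_elovich <- function(data) {
  .kin_check(data)
  keep <- data$t > 0
  if (sum(keep) < 3) stop("need at least 3 points with t > 0")
  ols <- .ols(log(data$t[keep]), data$qt[keep])
  s <- ols$slope; i <- ols$intercept
  beta <- 1 / s
  alpha <- s * exp(i / s)                  # from ln(alpha beta) = i/s
  sd_beta <- ols$se_slope / s^2
  # alpha = s exp(i/s): grad = (exp(i/s), exp(i/s) (1 - i/s))
  sd_alpha <- .delta_sd(c(exp(i / s), exp(i / s) * (1 - i / s)), ols$cov)
  model_fit(
    "elovich",
    parameters = c(alpha = alpha, beta = beta),
    parameter_sd = c(alpha = sd_alpha, beta = sd_beta),
    r_squared = ols$r_squared,
    fit_mode = "linearized",
    units = c(alpha = "mg g-1 min-1", beta = "g mg-1"),
    details = list(linear_form = "qt ~ ln(t)")
  )
}

#' Rank kinetic fits and flag equilibrium-capacity disagreement
#'
#' Orders fits by R-squared and flags any model whose fitted equilibrium
#' capacity deviates from the experimental plateau `qe_exp` by more than
#' `rel_threshold` as "rejected despite fit quality" - the standard
#' diagnostic by which a well-correlated pseudo-first-order fit is
#' discarded when its qe is far from the measured value.
#'
#' @param fits list of `adsorb_fit` objects (any subset of the kinetic
#'   models; an empty list yields an empty report).
#' @param qe_exp experimental equilibrium capacity (mg g-1).
#' @param rel_threshold relative deviation above which a model is flagged
#'   (default 0.2, i.e. 20 percent).
#' @return An object of class `kinetic_selection`: a data.frame with one
#'   row per fit (`model`, `r_squared`, `qe_fit`, `qe_rel_dev`, `flagged`),
#'   ranked best first.
#' @export
select_kinetic_model <- function(fits, qe_exp, rel_threshold = 0.2) {
  if (length(fits) == 0) {
    out <- data.frame(model = character(), r_squared = numeric(),
                      qe_fit = numeric(), qe_rel_dev = numeric(),
                      flagged = logical(), rank = integer())
    return(structure(out, qe_exp = if (missing(qe_exp)) NA_real_ else qe_exp,
                     class = c("kinetic_selection", "data.frame")))
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "adsorb_fit")))
  qe_fit <- vapply(fits, function(f) {
    if ("qe" %in% names(f$parameters)) f$parameters[["qe"]] else NA_real_
  }, numeric(1))
  rel_dev <- abs(qe_fit - qe_exp) / qe_exp
  out <- data.frame(
    model = vapply(fits, function(f) f$model_name, character(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    qe_fit = qe_fit,
    qe_rel_dev = rel_dev,
    flagged = !is.na(rel_dev) & rel_dev > rel_threshold,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$r_squared), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, qe_exp = qe_exp, rel_threshold = rel_threshold,
            class = c("kinetic_selection", "data.frame"))
}

#' @export
print.kinetic_selection <- function(x, ...) {
  cat(sprintf("Kinetic model selection (qe_exp = %g mg/g)\n",
              attr(x, "qe_exp")))
  df <- as.data.frame(x)
  if (nrow(df) == 0) {
    cat("  (no fits)\n")
    return(invisible(x))
  }
  df$flagged <- ifelse(df$flagged, "rejected despite fit quality", "")
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
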