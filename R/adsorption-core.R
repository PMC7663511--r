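#' nanosorb: adsorption analysis of doxorubicin on carbon nanotubes
#'
#' Batch-uptake mass balances, equilibrium isotherm and kinetic model fitting,
#' zigzag nanotube coordinate generation, and aggregate/interior metrics for
#' point-reduced molecular configurations, with synthetic-data generators
#' carrying exact ground truth.
#'
#' @keywords internal
#' @importFrom stats lm coef vcov rnorm runif median setNames var predict residuals fitted
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

#' Gas constant in kJ mol-1 K-1
#'
#' Used by the Temkin isotherm, whose slope is RT/b with b in kJ mol-1.
#' @export
R_GAS_KJ <- 8.314e-3

## ---- batch experiment -------------------------------------------------

#' Describe one batch adsorption mixture
#'
#' A batch experiment mixes a known volume of adsorbate solution with a known
#' mass of adsorbent; uptake is inferred from the drop in solution
#' concentration. Units follow the mass-balance convention: volumes in mL,
#' masses in g, concentrations in mg mL-1, capacities in mg g-1.
#'
#' @param volume_ml total liquid volume V (mL).
#' @param mass_g adsorbent mass m (g).
#' @param c0 initial adsorbate concentration (mg mL-1).
#' @param c measured concentration (mg mL-1): the equilibrium value Ce or a
#'   time-point value Ct.
#' @param time_min sampling time in minutes (NA for equilibrium experiments).
#' @param temperature_k temperature (K).
#' @return An object of class `batch_experiment`.
#' @examples
#' be <- batch_experiment(4.5, 3e-4, c0 = 0.533, c = 0.2797)
#' capacity_at_equilibrium(be)
#' @export
batch_experiment <- function(volume_ml, mass_g, c0, c,
                             time_min = NA_real_, temperature_k = 298.15) {
  stopifnot(is.numeric(volume_ml), is.numeric(mass_g),
            is.numeric(c0), is.numeric(c))
  if (volume_ml <= 0) stop("total volume must be positive")
  if (mass_g <= 0) stop("adsorbent mass must be positive")
  if (c0 < 0) stop("initial concentration must be non-negative")
  if (c < 0) stop("measured concentration must be non-negative")
  if (c > c0) {
    stop("measured concentration (", signif(c, 6),
         ") exceeds the initial concentration (", signif(c0, 6),
         "): inconsistent batch experiment")
  }
  structure(
    list(volume_ml = volume_ml, mass_g = mass_g, c0 = c0, c = c,
         time_min = time_min, temperature_k = temperature_k),
    class = "batch_experiment"
  )
}

#' @export
print.batch_experiment <- function(x, ...) {
  cat("Batch adsorption experiment\n")
  cat(sprintf("  V = %g mL, m = %g g, T = %g K\n",
              x$volume_ml, x$mass_g, x$temperature_k))
  cat(sprintf("  C0 = %g mg/mL, C = %g mg/mL%s\n", x$c0, x$c,
              if (is.na(x$time_min)) " (equilibrium)"
              else sprintf(" at t = %g min", x$time_min)))
  invisible(x)
}

#' Equilibrium adsorption capacity from a batch mass balance
#'
#' Computes `qe = V (C0 - Ce) / m`, the mass of adsorbate bound per unit mass
#' of adsorbent once the solution concentration has settled at Ce.
#'
#' @param exp a [batch_experiment()] whose `c` slot holds the equilibrium
#'   concentration Ce.
#' @return Capacity qe in mg g-1 (non-negative).
#' @export
capacity_at_equilibrium <- function(exp) {
  stopifnot(inherits(exp, "batch_experiment"))
  exp$volume_ml * (exp$c0 - exp$c) / exp$mass_g
}

#' Time-point adsorption capacity from a batch mass balance
#'
#' Computes `qt = V (C0 - Ct) / m` for a mixture sampled at time t. The
#' formula is identical to the equilibrium balance with Ct in place of Ce.
#'
#' @param exp a [batch_experiment()] whose `c` slot holds the concentration
#'   Ct measured at `time_min`.
#' @return Capacity qt in mg g-1.
#' @export
capacity_at_time <- function(exp) {
  capacity_at_equilibrium(exp)
}

## ---- spectrophotometric calibration ----------------------------------

#' Fit a spectrophotometric standard curve
#'
#' Ordinary least squares of absorbance on concentration over a set of
#' standards, as used to back-calculate solution concentrations at a fixed
#' wavelength (484 nm for doxorubicin).
#'
#' @param concentration standard concentrations (mg mL-1), at least 3
#'   distinct values.
#' @param absorbance measured absorbances (dimensionless).
#' @param wavelength_nm detection wavelength (nm).
#' @return An object of class `calibration_curve` with fields `slope`
#'   (absorbance per mg mL-1), `intercept`, `wavelength_nm`, `r_squared`.
#' @export
fit_calibration <- function(concentration, absorbance, wavelength_nm = 484) {
  stopifnot(is.numeric(concentration), is.numeric(absorbance),
            length(concentration) == length(absorbance))
  if (length(concentration) < 3)
    stop("calibration requires at least 3 standards")
  if (length(unique(concentration)) < 2 || var(concentration) == 0)
    stop("calibration standards have zero concentration variance")
  fit <- lm(absorbance ~ concentration)
  cf <- coef(fit)
  sst <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
  calibration_curve(slope = unname(cf[2]), intercept = unname(cf[1]),
                    wavelength_nm = wavelength_nm, r_squared = r2)
}

#' @rdname fit_calibration
#' @param slope,intercept,r_squared line parameters, for direct construction.
#' @export
calibration_curve <- function(slope, intercept, wavelength_nm = 484,
                              r_squared = NA_real_) {
  if (!is.na(slope) && slope <= 0)
    stop("calibration slope must be positive (absorbance grows with concentration)")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  structure(
    list(slope = slope, intercept = intercept,
         wavelength_nm = wavelength_nm, r_squared = r_squared),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve at %g nm: A = %.6g * C + %.6g  (R^2 = %.4f)\n",
    x$wavelength_nm, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a standard curve
#'
#' Back-calculates concentration from absorbance, `C = (A - intercept) /
#' slope`. Negative results (absorbance below the blank, i.e. measurement
#' noise) are clipped to zero with a warning rather than rejected.
#'
#' @param curve a [calibration_curve()].
#' @param absorbance measured absorbance(s).
#' @return Concentration(s) in mg mL-1, clipped at 0.
#' @export
concentration_from_absorbance <- function(curve, absorbance) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.na(curve$slope) || curve$slope == 0)
    stop("calibration slope must be nonzero to invert")
  conc <- (absorbance - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning(sum(conc < 0),
            " back-calculated concentration(s) below zero clipped to 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' @rdname concentration_from_absorbance
#' @param concentration concentration(s) in mg mL-1.
#' @export
absorbance_from_concentration <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * concentration + curve$intercept
}

## ---- reference fixture ------------------------------------------------

#' Reference batch mixture for the modified-nanotube experiments
#'
#' Encodes the documented mixture geometry: 300 uL of a 1 mg mL-1 nanotube
#' suspension (so m = 3e-4 g of adsorbent) in a total volume of 4500 uL,
#' with a configurable initial drug concentration.
#'
#' @param c0 initial drug concentration (mg mL-1).
#' @param c measured concentration (mg mL-1).
#' @param ... passed to [batch_experiment()].
#' @return A [batch_experiment()].
#' @export
reference_batch <- function(c0 = 0.533, c, ...) {
  batch_experiment(volume_ml = 4.5, mass_g = 3e-4, c0 = c0, c = c, ...)
}
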