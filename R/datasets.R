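## Measurement containers and their CSV / JSON interfaces.

#' Equilibrium isotherm dataset
#'
#' Ordered (Ce, qe) pairs at a fixed temperature. Log-linearized isotherm
#' fits require strictly positive Ce; qe must be non-negative and at least
#' three points are needed for any fit.
#'
#' @param ce equilibrium concentrations (mg mL-1), all > 0.
#' @param qe equilibrium capacities (mg g-1), all >= 0.
#' @param temperature_k temperature (K).
#' @return An object of class `isotherm_dataset`: a data.frame with columns
#'   `Ce`, `qe` and a `temperature_k` attribute.
#' @export
isotherm_dataset <- function(ce, qe, temperature_k = 298.15) {
  stopifnot(is.numeric(ce), is.numeric(qe), length(ce) == length(qe))
  if (length(ce) < 3)
    stop("an isotherm dataset needs at least 3 points")
  if (any(ce <= 0)) {
    bad <- which(ce <= 0)[1]
    stop("Ce must be positive for log-linearized fits; row ", bad,
         " has Ce = ", ce[bad])
  }
  if (any(qe < 0)) {
    bad <- which(qe < 0)[1]
    stop("qe must be non-negative; row ", bad, " has qe = ", qe[bad])
  }
  ord <- order(ce)
  structure(
    data.frame(Ce = ce[ord], qe = qe[ord]),
    temperature_k = temperature_k,
    class = c("isotherm_dataset", "data.frame")
  )
}

#' Adsorption kinetics dataset
#'
#' Ordered (t, qt) pairs, optionally with the experimentally observed
#' equilibrium capacity (needed by the pseudo-first-order linearization).
#'
#' @param t sampling times (min), non-negative and strictly increasing.
#' @param qt capacities at time t (mg g-1), all >= 0.
#' @param qe_exp experimental equilibrium capacity (mg g-1), or NULL.
#' @return An object of class `kinetic_dataset`: a data.frame with columns
#'   `t`, `qt` and a `qe_exp` attribute.
#' @export
kinetic_dataset <- function(t, qt, qe_exp = NULL) {
  stopifnot(is.numeric(t), is.numeric(qt), length(t) == length(qt))
  if (any(t < 0)) stop("times must be non-negative")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (any(qt < 0)) {
    bad <- which(qt < 0)[1]
    stop("qt must be non-negative; row ", bad, " has qt = ", qt[bad])
  }
  if (!is.null(qe_exp)) stopifnot(is.numeric(qe_exp), qe_exp > 0)
  structure(
    data.frame(t = t, qt = qt),
    qe_exp = qe_exp,
    class = c("kinetic_dataset", "data.frame")
  )
}

#' The twelve standard sampling times of the kinetic experiments (min)
#' @export
KINETIC_TIMES_MIN <- c(1, 3, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90)

## ---- CSV interface ----------------------------------------------------

#' Read an isotherm dataset from CSV
#'
#' Expects exactly the header `Ce,qe` (UTF-8, decimal point). Column names
#' are validated strictly so that unit mix-ups fail loudly.
#'
#' @param path CSV file path.
#' @param temperature_k temperature to attach (K).
#' @return An [isotherm_dataset()].
#' @export
read_isotherm_csv <- function(path, temperature_k = 298.15) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (!identical(names(df), c("Ce", "qe")))
    stop("expected columns 'Ce,qe' in ", path, "; found: ",
         paste(names(df), collapse = ","))
  isotherm_dataset(df$Ce, df$qe, temperature_k = temperature_k)
}

#' Read a kinetics dataset from CSV
#'
#' Accepts either the header `t,qt` (capacities already computed) or `t,Ct`
#' (raw time-point concentrations); in the latter case the batch mixture
#' parameters must be supplied so the mass balance can convert Ct to qt.
#'
#' @param path CSV file path.
#' @param qe_exp experimental equilibrium capacity (mg g-1), optional.
#' @param volume_ml,mass_g,c0 batch mixture parameters, required when the
#'   file holds `t,Ct`.
#' @return A [kinetic_dataset()].
#' @export
read_kinetic_csv <- function(path, qe_exp = NULL,
                             volume_ml = NULL, mass_g = NULL, c0 = NULL) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (identical(names(df), c("t", "qt"))) {
    return(kinetic_dataset(df$t, df$qt, qe_exp = qe_exp))
  }
  if (identical(names(df), c("t", "Ct"))) {
    if (is.null(volume_ml) || is.null(mass_g) || is.null(c0))
      stop("columns 't,Ct' require volume_ml, mass_g and c0 to convert ",
           "concentrations to capacities")
    qt <- vapply(df$Ct, function(ct)
      capacity_at_time(batch_experiment(volume_ml, mass_g, c0, ct)),
      numeric(1))
    return(kinetic_dataset(df$t, qt, qe_exp = qe_exp))
  }
  stop("expected columns 't,qt' or 't,Ct' in ", path, "; found: ",
       paste(names(df), collapse = ","))
}

#' Write a dataset to CSV
#'
#' @param x an [isotherm_dataset()] or [kinetic_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(x, path) {
  stopifnot(inherits(x, c("isotherm_dataset", "kinetic_dataset")))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

## ---- JSON interface ---------------------------------------------------

#' Serialize a nanosorb object to JSON
#'
#' Every domain type serializes to a tagged JSON object that
#' [deserialize_json()] reconstructs (round-trip stable: structure and
#' names exactly, numeric payloads to the 15-significant-digit limit of
#' decimal text).
#'
#' @param x a `batch_experiment`, `calibration_curve`, `isotherm_dataset`,
#'   `kinetic_dataset` or `adsorb_fit`.
#' @param path optional file path; when given, JSON is written there.
#' @return JSON text (invisibly, when `path` is given).
#' @export
serialize_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "batch_experiment")) {
    c(list(type = "batch_experiment"), unclass(x))
  } else if (inherits(x, "calibration_curve")) {
    c(list(type = "calibration_curve"), unclass(x))
  } else if (inherits(x, "isotherm_dataset")) {
    list(type = "isotherm_dataset", Ce = x$Ce, qe = x$qe,
         temperature_k = attr(x, "temperature_k"))
  } else if (inherits(x, "kinetic_dataset")) {
    list(type = "kinetic_dataset", t = x$t, qt = x$qt,
         qe_exp = attr(x, "qe_exp"))
  } else if (inherits(x, "adsorb_fit")) {
    p <- c(list(type = "adsorb_fit"), unclass(x))
    p$parameters <- as.list(x$parameters)     # keep names in JSON objects
    p$parameter_sd <- as.list(x$parameter_sd)
    if (!is.null(x$units)) p$units <- as.list(x$units)
    p$details <- Filter(function(el) !is.function(el), x$details)
    p
  } else {
    stop("no JSON serialization for class ", paste(class(x), collapse = "/"))
  }
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname serialize_json
#' @param json JSON text or a file path to read.
#' @export
deserialize_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)  # JSON "40" reads as integer
  switch(obj$type,
    batch_experiment = batch_experiment(
      num(obj$volume_ml), num(obj$mass_g), num(obj$c0), num(obj$c),
      time_min = if (is.null(obj$time_min)) NA_real_ else num(obj$time_min),
      temperature_k = num(obj$temperature_k)),
    calibration_curve = calibration_curve(
      num(obj$slope), num(obj$intercept), num(obj$wavelength_nm),
      num(obj$r_squared)),
    isotherm_dataset = isotherm_dataset(
      num(obj$Ce), num(obj$qe), temperature_k = num(obj$temperature_k)),
    kinetic_dataset = kinetic_dataset(num(obj$t), num(obj$qt),
                                      qe_exp = num(obj$qe_exp)),
    adsorb_fit = model_fit(
      model_name = obj$model_name,
      parameters = setNames(num(unlist(obj$parameters)),
                            names(obj$parameters)),
      parameter_sd = setNames(num(unlist(obj$parameter_sd)),
                              names(obj$parameter_sd)),
      r_squared = num(obj$r_squared),
      fit_mode = obj$fit_mode,
      valid = obj$valid,
      units = if (is.null(obj$units)) NULL else unlist(obj$units),
      details = if (is.null(obj$details)) list() else as.list(obj$details)),
    stop("unknown serialized type: ", obj$type)
  )
}
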