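## End-to-end report assembly: a single YAML config drives data generation
## or ingestion, isotherm and kinetic fitting, model selection, and
## trajectory metrics, writing a deterministic bundle of JSON/CSV artifacts
## plus a run log. Every tunable default (cutoffs, radii, thresholds) lives
## in the config, not in code constants.

.config_schema <- list(
  seed = "integer",
  temperature_k = "number",
  isotherm = list(
    csv = "string?", model = "string?", params = "list?",
    ce_min = "number?", ce_max = "number?", n_points = "integer?",
    noise_sd = "number?", mode = "string?"
  ),
  kinetics = list(
    csv = "string?", model = "string?", params = "list?",
    t_points = "numbers?", noise_sd = "number?", qe_exp = "number?",
    n_segments = "integer?", qe_rel_threshold = "number?"
  ),
  trajectory = list(
    xyz = "string?", tube_n = "integer?", tube_length_nm = "number?",
    diameters_nm = "numbers?", box = "numbers?",
    n_inside = "integer?", surface_clusters = "integers?",
    free_clusters = "integers?", min_separation = "number?",
    cluster_cutoff = "number?", contact_cutoff = "number?",
    sphere_radius = "number?", mode = "string?"
  )
)

.validate_config <- function(cfg) {
  problems <- character(0)
  check <- function(node, schema, path) {
    for (key in names(node)) {
      if (!key %in% names(schema))
        problems <<- c(problems, paste0(path, key, ": unknown field"))
    }
    for (key in names(schema)) {
      spec <- schema[[key]]
      val <- node[[key]]
      if (is.list(spec)) {
        if (!is.null(val)) {
          if (!is.list(val))
            problems <<- c(problems, paste0(path, key, ": must be a mapping"))
          else check(val, spec, paste0(path, key, "."))
        }
        next
      }
      optional <- grepl("\\?$", spec)
      type <- sub("\\?$", "", spec)
      if (is.null(val)) {
        if (!optional)
          problems <<- c(problems, paste0(path, key, ": required"))
        next
      }
      ok <- switch(type,
        integer = is.numeric(val) && length(val) == 1 &&
                  val == round(val),
        number = is.numeric(val) && length(val) == 1,
        numbers = is.numeric(val),
        integers = is.numeric(val) && all(val == round(val)),
        string = is.character(val) && length(val) == 1,
        list = is.list(val),
        TRUE)
      if (!ok)
        problems <<- c(problems, paste0(path, key, ": expected ", type))
    }
  }
  check(cfg, .config_schema, "")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages are driven by which sections the config contains: `isotherm`
#' (generate from a named model or read a CSV, fit and rank all three
#' isotherms), `kinetics` (generate or read, fit all five kinetic models,
#' run capacity-agreement model selection), `trajectory` (build the tube,
#' plant a configuration or read an XYZ trajectory, compute aggregate
#' metrics). All randomness flows through the config `seed`; identical
#' config and seed give identical numeric payloads. Inputs are never
#' mutated.
#'
#' @param config a YAML file path or an equivalent named list. Required
#'   top-level fields: `seed`, `temperature_k`. Missing files and malformed
#'   files raise distinct errors; schema violations are reported with their
#'   field paths.
#' @param output_dir optional directory: per-model fit JSONs, the selection
#'   report, the aggregate CSV and a run log are written there.
#' @return A list bundle with elements `config`, `isotherm`
#'   (`comparison`), `kinetics` (`fits`, `selection`), `trajectory`
#'   (`report`), and `log` (character vector).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- tryCatch(yaml::read_yaml(config),
                    error = function(e) stop("malformed config file '",
                                             config, "': ",
                                             conditionMessage(e)))
  } else if (is.list(config)) {
    cfg <- config
  } else stop("config must be a file path or a list")
  .validate_config(cfg)
  seed <- as.integer(cfg$seed)
  log <- c(
    paste0("nanosorb ", as.character(utils::packageVersion("nanosorb")),
           " | R ", paste(R.version$major, R.version$minor, sep = ".")),
    paste0("seed: ", seed),
    paste0("config: ", gsub("\n", " | ",
                            yaml::as.yaml(cfg, line.sep = "\n")))
  )
  bundle <- list(config = cfg)

  if (!is.null(cfg$isotherm)) {
    iso <- cfg$isotherm
    data <- if (!is.null(iso$csv)) {
      if (!file.exists(iso$csv)) stop("isotherm.csv file not found: ", iso$csv)
      read_isotherm_csv(iso$csv, temperature_k = cfg$temperature_k)
    } else {
      gen_isotherm(iso$model, iso$params,
                   ce_grid = exp(seq(log(iso$ce_min %||% 0.067),
                                     log(iso$ce_max %||% 0.533),
                                     length.out = iso$n_points %||% 20)),
                   noise_sd = iso$noise_sd %||% 0.01,
                   seed = seed, temperature_k = cfg$temperature_k)
    }
    cmp <- compare_isotherms(data, mode = iso$mode %||% "linearized",
                             temperature_k = cfg$temperature_k)
    bundle$isotherm <- list(data = data, comparison = cmp)
    log <- c(log, paste0("isotherm: ", nrow(data), " points; best model: ",
                         cmp$ranking$model[1]))
  }

  if (!is.null(cfg$kinetics)) {
    kin <- cfg$kinetics
    data <- if (!is.null(kin$csv)) {
      if (!file.exists(kin$csv)) stop("kinetics.csv file not found: ", kin$csv)
      read_kinetic_csv(kin$csv, qe_exp = kin$qe_exp)
    } else {
      gen_kinetics(kin$model, kin$params,
                   t_points = kin$t_points %||% KINETIC_TIMES_MIN,
                   noise_sd = kin$noise_sd %||% 0.01,
                   seed = seed + 1L, qe_exp = kin$qe_exp)
    }
    qe_exp <- attr(data, "qe_exp") %||% max(data$qt)
    fits <- list(
      pseudo_first = tryCatch(fit_pseudo_first(data, qe_exp),
                              error = function(e) NULL),
      pseudo_second = tryCatch(fit_pseudo_second(data),
                               error = function(e) NULL),
      intraparticle = tryCatch(
        fit_intraparticle(data, n_segments = kin$n_segments %||% 2),
        error = function(e) NULL),
      fractional_power = tryCatch(fit_fractional_power(data),
                                  error = function(e) NULL),
      elovich = tryCatch(fit_elovich(data), error = function(e) NULL)
    )
    fits <- Filter(Negate(is.null), fits)
    selection <- select_kinetic_model(
      fits, qe_exp, rel_threshold = kin$qe_rel_threshold %||% 0.2)
    bundle$kinetics <- list(data = data, fits = fits, selection = selection)
    log <- c(log, paste0("kinetics: ", nrow(data), " points; top model: ",
                         selection$model[1]))
  }

  if (!is.null(cfg$trajectory)) {
    trj <- cfg$trajectory
    frames <- if (!is.null(trj$xyz)) {
      if (!file.exists(trj$xyz))
        stop("trajectory.xyz file not found: ", trj$xyz)
      read_xyz(trj$xyz)
    } else {
      box <- trj$box %||% c(20, 80, 20)
      walls <- if (!is.null(trj$diameters_nm)) {
        build_mwcnt(trj$diameters_nm,
                    length_nm = trj$tube_length_nm %||% 20,
                    origin = c(box[1] / 2,
                               (box[2] - (trj$tube_length_nm %||% 20)) / 2,
                               box[3] / 2))
      } else {
        list(build_zigzag(nanotube_spec(
          trj$tube_n %||% 82L, length_nm = trj$tube_length_nm %||% 20,
          origin = c(box[1] / 2,
                     (box[2] - (trj$tube_length_nm %||% 20)) / 2,
                     box[3] / 2))))
      }
      list(plant_configuration(
        walls,
        n_inside = trj$n_inside %||% 5,
        surface_clusters = trj$surface_clusters %||% c(10, 10),
        free_clusters = trj$free_clusters %||% c(4, 4, 4),
        min_separation = trj$min_separation %||% 2.0,
        box = box, seed = seed + 2L))
    }
    report <- analyze_trajectory(
      frames,
      cluster_cutoff = trj$cluster_cutoff %||% 1.0,
      contact_cutoff = trj$contact_cutoff %||% 0.5,
      sphere_radius = trj$sphere_radius,
      mode = trj$mode %||% "cluster")
    bundle$trajectory <- list(report = report)
    log <- c(log, paste0("trajectory: ", nrow(report), " frame(s)"))
  }

  bundle$log <- log
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(bundle$isotherm)) {
      for (nm in names(bundle$isotherm$comparison$fits))
        serialize_json(bundle$isotherm$comparison$fits[[nm]],
                       file.path(output_dir, paste0("isotherm_", nm, ".json")))
    }
    if (!is.null(bundle$kinetics)) {
      for (nm in names(bundle$kinetics$fits)) {
        fit <- bundle$kinetics$fits[[nm]]
        fit$details$predict <- NULL        # closures do not serialize
        fit$details$segments <- NULL
        serialize_json(fit,
                       file.path(output_dir, paste0("kinetic_", nm, ".json")))
      }
      write.csv(as.data.frame(bundle$kinetics$selection),
                file.path(output_dir, "kinetic_selection.csv"),
                row.names = FALSE, quote = FALSE)
    }
    if (!is.null(bundle$trajectory))
      write.csv(as.data.frame(bundle$trajectory$report),
                file.path(output_dir, "aggregate_report.csv"),
                row.names = FALSE, quote = FALSE)
    writeLines(log, file.path(output_dir, "run.log"))
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Human-readable summary of a pipeline bundle
#'
#' Assembles one table row per fitted model (parameters with standard
#' deviations and R-squared, in the familiar two-table layout of adsorption
#' studies) plus the per-frame aggregate metrics, and prints it. An empty
#' bundle yields a header-only table.
#'
#' @param bundle a [run_pipeline()] result.
#' @return Invisibly, a data.frame with columns `stage`, `model`,
#'   `parameter`, `value`, `sd`, `r_squared`.
#' @export
render_summary <- function(bundle) {
  rows <- list()
  fit_rows <- function(stage, fit) {
    data.frame(stage = stage, model = fit$model_name,
               parameter = names(fit$parameters),
               value = unname(fit$parameters),
               sd = unname(fit$parameter_sd),
               r_squared = fit$r_squared,
               stringsAsFactors = FALSE)
  }
  if (!is.null(bundle$isotherm)) {
    for (fit in bundle$isotherm$comparison$fits)
      rows[[length(rows) + 1L]] <- fit_rows("isotherm", fit)
  }
  if (!is.null(bundle$kinetics)) {
    for (fit in bundle$kinetics$fits)
      rows[[length(rows) + 1L]] <- fit_rows("kinetics", fit)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(), model = character(),
               parameter = character(), value = numeric(), sd = numeric(),
               r_squared = numeric())
  rownames(out) <- NULL
  cat("Model fits\n")
  if (nrow(out)) print(out, row.names = FALSE, digits = 5) else
    cat("  (none)\n")
  if (!is.null(bundle$trajectory)) {
    cat("\nAggregate metrics\n")
    print(as.data.frame(bundle$trajectory$report), row.names = FALSE,
          digits = 4)
  }
  invisible(out)
}
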