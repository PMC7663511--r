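## Multi-frame XYZ reader/writer. Standard layout per frame:
##
##   <atom count>
##   time_ns=<t> box=<lx>,<ly>,<lz>
##   C  x y z      (nanotube carbons, all walls in order)
##   X  x y z      (point-reduced drug molecules)
##
## Element tags carry the grouping: "C" = tube atoms, "X" = molecule centers
## of mass. Wall boundaries and ring indices do not fit the XYZ format and
## travel in a sidecar JSON written next to the file.

#' Write a trajectory (or single configuration) to an XYZ file
#'
#' @param frames a [molecular_configuration()] or list of them.
#' @param path output XYZ path.
#' @param sidecar write `<path>.json` holding wall atom counts and ring
#'   indices so [read_xyz()] can reconstruct walls exactly.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, sidecar = TRUE) {
  if (inherits(frames, "molecular_configuration")) frames <- list(frames)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cfg in frames) {
    stopifnot(inherits(cfg, "molecular_configuration"))
    wall_atoms <- sum(vapply(cfg$walls, nrow, integer(1)))
    n <- wall_atoms + nrow(cfg$dox)
    writeLines(as.character(n), con)
    writeLines(sprintf("time_ns=%.10g box=%.10g,%.10g,%.10g",
                       cfg$time_ns, cfg$box[1], cfg$box[2], cfg$box[3]), con)
    for (w in cfg$walls) {
      writeLines(sprintf("C %.9f %.9f %.9f", w[, 1], w[, 2], w[, 3]), con)
    }
    if (nrow(cfg$dox) > 0)
      writeLines(sprintf("X %.9f %.9f %.9f",
                         cfg$dox[, 1], cfg$dox[, 2], cfg$dox[, 3]), con)
  }
  if (sidecar && length(frames) > 0) {
    walls0 <- frames[[1]]$walls
    idx <- list(
      wall_sizes = vapply(walls0, nrow, integer(1)),
      ring_index = lapply(walls0, function(w) {
        ri <- attr(w, "ring_index")
        if (is.null(ri)) integer(0) else as.integer(ri)
      }),
      radius_nm = vapply(walls0, .wall_radius, numeric(1))
    )
    jsonlite::write_json(idx, paste0(path, ".json"), auto_unbox = FALSE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Atoms tagged "C" become nanotube wall atoms, atoms tagged "X" molecule
#' centers of mass. When a sidecar JSON (written by [write_xyz()]) is
#' present or given, the carbons are split back into walls with their ring
#' indices; otherwise all carbons form one wall.
#'
#' @param path XYZ file path.
#' @param sidecar sidecar JSON path; defaults to `<path>.json` when that
#'   file exists.
#' @return List of [molecular_configuration()] frames.
#' @export
read_xyz <- function(path, sidecar = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (is.null(sidecar) && file.exists(paste0(path, ".json")))
    sidecar <- paste0(path, ".json")
  idx <- if (!is.null(sidecar))
    jsonlite::fromJSON(sidecar, simplifyMatrix = FALSE) else NULL
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    header <- lines[i + 1L]
    tm <- .xyz_field(header, "time_ns")
    box <- as.numeric(strsplit(.xyz_field(header, "box", "20,80,20"),
                               ",")[[1]])
    if (length(box) != 3 || any(is.na(box)))
      stop("malformed XYZ comment line ", i + 1L, ": bad box spec")
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    elem <- vapply(parts, `[`, character(1), 1)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(coords))) stop("malformed XYZ coordinates near line ", i)
    carbons <- coords[elem == "C", , drop = FALSE]
    dox <- coords[elem == "X", , drop = FALSE]
    walls <- if (nrow(carbons) == 0) {
      list()
    } else if (!is.null(idx) && length(idx$wall_sizes) > 0) {
      if (sum(idx$wall_sizes) != nrow(carbons))
        stop("sidecar wall sizes do not match carbon count in frame")
      stops <- cumsum(idx$wall_sizes)
      starts <- c(1L, head(stops, -1) + 1L)
      lapply(seq_along(stops), function(k) {
        w <- carbons[starts[k]:stops[k], , drop = FALSE]
        ri <- idx$ring_index[[k]]
        if (length(ri)) attr(w, "ring_index") <- as.integer(ri)
        if (!is.null(idx$radius_nm)) attr(w, "radius_nm") <- idx$radius_nm[k]
        w
      })
    } else {
      list(carbons)
    }
    frames[[length(frames) + 1L]] <-
      molecular_configuration(dox, walls, box,
                              time_ns = as.numeric(tm))
    i <- i + 2L + n
  }
  frames
}

.xyz_field <- function(header, key, default = NA_character_) {
  m <- regmatches(header,
                  regexec(paste0(key, "=([^ ]+)"), header))[[1]]
  if (length(m) == 2) m[2] else default
}
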