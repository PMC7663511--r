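## Configuration metrics for point-reduced drug molecules around a nanotube:
## single-linkage aggregate detection (union-find), adsorbed fraction, and
## the ring-decomposition interior-occupancy count. All distances use the
## minimum-image convention under the periodic box; the nanotube itself is
## never wrapped across the box.

#' Molecular configuration of point-reduced drug molecules and a nanotube
#'
#' @param dox numeric matrix (N x 3, nm) of molecule centers of mass; a
#'   0-row matrix is an allowed empty configuration.
#' @param walls list of `cnt_wall` matrices (innermost first) or an empty
#'   list when no nanotube is present.
#' @param box periodic box lengths (3 values, nm).
#' @param time_ns frame time stamp (ns).
#' @return An object of class `molecular_configuration`.
#' @export
molecular_configuration <- function(dox, walls = list(), box,
                                    time_ns = NA_real_) {
  if (is.null(dim(dox))) dox <- matrix(dox, ncol = 3)
  dimnames(dox) <- NULL
  stopifnot(is.numeric(dox), ncol(dox) == 3)
  if (nrow(dox) > 0 && !all(is.finite(dox)))
    stop("molecule coordinates must all be finite")
  stopifnot(is.list(walls), length(box) == 3, all(box > 0))
  for (w in walls) {
    stopifnot(is.matrix(w), ncol(w) == 3)
    if (!all(is.finite(w))) stop("wall coordinates must all be finite")
  }
  if (length(walls) > 1) {
    radii <- vapply(walls, .wall_radius, numeric(1))
    if (is.unsorted(radii))
      stop("walls must be ordered innermost first (increasing radius)")
  }
  structure(
    list(dox = dox, walls = walls, box = as.numeric(box), time_ns = time_ns),
    class = "molecular_configuration"
  )
}

#' @export
print.molecular_configuration <- function(x, ...) {
  cat(sprintf(
    "Configuration at t = %s ns: %d molecules, %d wall(s), box %s nm\n",
    format(x$time_ns), nrow(x$dox), length(x$walls),
    paste(format(x$box), collapse = " x ")))
  invisible(x)
}

## Mean radial distance of wall atoms from their common axis; uses the
## builder spec when carried, otherwise the centroid/principal axis.
.wall_radius <- function(w) {
  if (!is.null(attr(w, "radius_nm"))) return(attr(w, "radius_nm"))
  ax <- .wall_axis(w)
  ctr <- colMeans(w)
  rel <- sweep(w, 2, ctr)
  axial <- drop(rel %*% ax)
  mean(sqrt(pmax(rowSums(rel^2) - axial^2, 0)))
}

.wall_axis <- function(w) {
  spec <- attr(w, "spec")
  if (!is.null(spec)) return(spec$axis)
  rel <- sweep(w, 2, colMeans(w))
  ev <- eigen(crossprod(rel), symmetric = TRUE)
  # For a cylinder the two radial eigenvalues coincide (~ N r^2 / 2); the
  # axis is the direction with the odd eigenvalue out, regardless of
  # whether the tube is longer or shorter than its diameter.
  odd <- which.max(abs(ev$values - median(ev$values)))
  ax <- ev$vectors[, odd]
  ax / sqrt(sum(ax^2))
}

## Minimum-image squared distances from one point to a matrix of points.
.mi_dist2 <- function(p, pts, box) {
  d <- sweep(pts, 2, p)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  rowSums(d^2)
}

#' Minimum-image distance between two points in a periodic box
#'
#' @param a,b 3-vectors (nm).
#' @param box box lengths (nm).
#' @return Euclidean distance to the nearest periodic image.
#' @export
min_image_distance <- function(a, b, box) {
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

## Union-find root lookup (iterative; trees stay shallow because unions
## always attach the second root under the first).
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Single-linkage aggregate detection
#'
#' Partitions the molecules of a configuration into aggregates: two
#' molecules belong to the same aggregate when a chain of center-of-mass
#' contacts closer than `cutoff` (minimum image) links them. When the
#' configuration carries a nanotube, the tube acts as one super-node joined
#' to every molecule lying within `contact_cutoff` of any wall atom, so
#' tube-adsorbed molecules and their linked clusters form a single
#' tube-containing aggregate. Implemented with a disjoint-set structure.
#'
#' @param config a [molecular_configuration()].
#' @param cutoff molecule-molecule linkage distance (nm).
#' @param contact_cutoff molecule-to-wall-atom contact distance (nm).
#' @return An object of class `aggregate_partition`: list with `labels`
#'   (integer aggregate id per molecule, 1..n_aggregates), `cnt_label`
#'   (the tube-containing aggregate id, or NA), `n_aggregates`, `sizes`.
#' @export
cluster_molecules <- function(config, cutoff = 1.0, contact_cutoff = 0.5) {
  stopifnot(inherits(config, "molecular_configuration"), cutoff > 0)
  n <- nrow(config$dox)
  if (n == 0) {
    return(structure(list(labels = integer(0), cnt_label = NA_integer_,
                          n_aggregates = 0L, sizes = integer(0)),
                     class = "aggregate_partition"))
  }
  has_cnt <- length(config$walls) > 0
  m <- n + as.integer(has_cnt)            # super-node index n + 1
  parent <- seq_len(m)
  union_ <- function(a, b) {
    ra <- .uf_find(parent, a); rb <- .uf_find(parent, b)
    if (ra != rb) parent[rb] <<- ra
  }
  cut2 <- cutoff^2
  if (n > 1) {
    for (i in 1:(n - 1)) {
      d2 <- .mi_dist2(config$dox[i, ], config$dox[(i + 1):n, , drop = FALSE],
                      config$box)
      for (j in which(d2 < cut2)) union_(i, i + j)
    }
  }
  if (has_cnt) {
    cc2 <- contact_cutoff^2
    allw <- do.call(rbind, lapply(config$walls, unclass))
    for (i in seq_len(n)) {
      if (min(.mi_dist2(config$dox[i, ], allw, config$box)) < cc2)
        union_(i, n + 1L)
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  cnt_root <- if (has_cnt) .uf_find(parent, n + 1L) else NA_integer_
  ids <- unique(roots)
  labels <- match(roots, ids)
  cnt_label <- if (!is.na(cnt_root) && cnt_root %in% ids)
    match(cnt_root, ids) else NA_integer_
  structure(
    list(labels = labels, cnt_label = cnt_label,
         n_aggregates = length(ids),
         sizes = tabulate(labels, nbins = length(ids))),
    class = "aggregate_partition"
  )
}

#' @export
print.aggregate_partition <- function(x, ...) {
  cat(sprintf("Aggregate partition: %d aggregate(s) over %d molecule(s)%s\n",
              x$n_aggregates, length(x$labels),
              if (is.na(x$cnt_label)) ""
              else sprintf(" (tube aggregate: #%d, %d molecules)",
                           x$cnt_label, x$sizes[x$cnt_label])))
  invisible(x)
}

#' Aggregate count and mean size
#'
#' Counts every aggregate (including the tube-containing one) and averages
#' the number of molecules per aggregate; the tube super-node is not
#' counted as a member.
#'
#' @param partition an [cluster_molecules()] result.
#' @return List with `n_aggregates` and `mean_size`.
#' @export
aggregate_stats <- function(partition) {
  stopifnot(inherits(partition, "aggregate_partition"))
  if (partition$n_aggregates == 0)
    return(list(n_aggregates = 0L, mean_size = NA_real_))
  list(n_aggregates = partition$n_aggregates,
       mean_size = length(partition$labels) / partition$n_aggregates)
}

#' Percentage of molecules adsorbed onto the nanotube
#'
#' Mode `"cluster"` (default) counts the molecules belonging to the
#' tube-containing aggregate - the convention under which a cluster docked
#' onto the tube counts as adsorbed in full. Mode `"contact"` counts only
#' molecules whose minimum distance to any wall atom is below
#' `contact_cutoff`.
#'
#' @param config a [molecular_configuration()] with at least one wall.
#' @param partition a [cluster_molecules()] partition (required for
#'   `"cluster"` mode; recomputed with defaults when missing).
#' @param contact_cutoff contact distance (nm) for `"contact"` mode.
#' @param mode `"cluster"` or `"contact"`.
#' @return Percentage (0 to 100) of all molecules.
#' @export
fraction_on_cnt <- function(config, partition = NULL, contact_cutoff = 0.5,
                            mode = c("cluster", "contact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "molecular_configuration"))
  if (length(config$walls) == 0)
    stop("configuration has no nanotube wall")
  n <- nrow(config$dox)
  if (n == 0) return(0)
  if (mode == "cluster") {
    if (is.null(partition))
      partition <- cluster_molecules(config, contact_cutoff = contact_cutoff)
    if (is.na(partition$cnt_label)) return(0)
    return(100 * partition$sizes[partition$cnt_label] / n)
  }
  allw <- do.call(rbind, lapply(config$walls, unclass))
  cc2 <- contact_cutoff^2
  hits <- vapply(seq_len(n), function(i)
    min(.mi_dist2(config$dox[i, ], allw, config$box)) < cc2, logical(1))
  100 * sum(hits) / n
}

#' Decompose a nanotube wall into parallel carbon rings
#'
#' Splits a wall into single carbon rings stacked along the tube axis.
#' Walls built by [build_zigzag()] carry their ring index and are split
#' exactly; a generic wall is grouped by axial coordinate, merging atoms
#' whose axial gap is below `tol`. Each detected ring must contain the same
#' number of atoms (at least 3); otherwise the offending axial position is
#' reported as a diagnostic error.
#'
#' @param wall a `cnt_wall` or plain atoms-x-3 matrix.
#' @param tol axial grouping tolerance (nm) for walls without ring indices.
#' @return An object of class `cnt_rings`: list with `centroids` (rings x 3
#'   matrix, ordered along the axis), `members` (list of atom index
#'   vectors), `axis`, `radius_nm`.
#' @export
decompose_rings <- function(wall, tol = 0.05) {
  stopifnot(is.matrix(wall), ncol(wall) == 3)
  axis <- .wall_axis(wall)
  axial <- drop(wall %*% axis)
  ring_index <- attr(wall, "ring_index")
  if (is.null(ring_index)) {
    ord <- order(axial)
    gaps <- diff(axial[ord])
    grp <- cumsum(c(1L, as.integer(gaps > tol)))
    ring_index <- integer(length(axial))
    ring_index[ord] <- grp
    counts <- tabulate(grp)
    if (length(unique(counts)) > 1 || any(counts < 3)) {
      bad <- which(counts != max(counts))[1]
      pos <- mean(axial[ord][grp == bad])
      stop("atoms not partitionable into uniform rings within tol = ", tol,
           " nm: axial group near ", signif(pos, 4), " nm has ",
           counts[bad], " atom(s)")
    }
  }
  members <- split(seq_len(nrow(wall)), ring_index)
  centroids <- t(vapply(members, function(idx)
    colMeans(wall[idx, , drop = FALSE]), numeric(3)))
  ord <- order(drop(centroids %*% axis))
  members <- members[ord]
  centroids <- centroids[ord, , drop = FALSE]
  structure(
    list(centroids = centroids, members = unname(members), axis = axis,
         radius_nm = .wall_radius(wall)),
    class = "cnt_rings"
  )
}

#' @export
print.cnt_rings <- function(x, ...) {
  cat(sprintf("Ring decomposition: %d rings of %d atoms, radius %.4f nm\n",
              nrow(x$centroids), length(x$members[[1]]), x$radius_nm))
  invisible(x)
}

#' Count molecules inside the nanotube channel
#'
#' The interior-occupancy algorithm: around the centroid of every carbon
#' ring, place a sphere of radius `sphere_radius` (smaller than the tube
#' radius); a molecule is inside the tube when its center of mass falls in
#' the union of these spheres. Molecules caught by several overlapping
#' spheres are counted once.
#'
#' @param config a [molecular_configuration()].
#' @param rings a [decompose_rings()] result for the innermost wall.
#' @param sphere_radius sphere radius (nm); default 0.9 x the ring radius.
#' @return List with `count` and `members` (molecule indices, sorted).
#' @export
count_inside <- function(config, rings, sphere_radius = NULL) {
  stopifnot(inherits(config, "molecular_configuration"),
            inherits(rings, "cnt_rings"))
  if (is.null(sphere_radius)) sphere_radius <- 0.9 * rings$radius_nm
  if (sphere_radius <= 0 || sphere_radius >= rings$radius_nm)
    stop("sphere_radius must lie in (0, tube radius = ",
         signif(rings$radius_nm, 4), " nm)")
  n <- nrow(config$dox)
  if (n == 0) return(list(count = 0L, members = integer(0)))
  r2 <- sphere_radius^2
  inside <- vapply(seq_len(n), function(i) {
    any(.mi_dist2(config$dox[i, ], rings$centroids, config$box) < r2)
  }, logical(1))
  list(count = sum(inside), members = which(inside))
}

#' Per-frame aggregate metrics over a trajectory
#'
#' Runs aggregate detection, adsorbed-fraction and interior-occupancy
#' counting on every frame, returning one report row per frame in time
#' order. Interior counting uses the innermost wall of each frame (skipped,
#' with NA, for frames without a tube).
#'
#' @param frames list of [molecular_configuration()] frames.
#' @param cluster_cutoff molecule-molecule linkage distance (nm).
#' @param contact_cutoff molecule-wall contact distance (nm).
#' @param sphere_radius interior sphere radius (nm); NULL for the 0.9 x
#'   tube-radius default.
#' @param mode adsorbed-fraction mode, `"cluster"` or `"contact"`.
#' @param csv optional path: the report is also written as a tidy CSV.
#' @return A data.frame of class `aggregate_report` with columns `time_ns`,
#'   `n_aggregates`, `mean_aggregate_size`, `fraction_on_cnt`,
#'   `fraction_inside_cnt` (percentages of all molecules); per-frame
#'   aggregate membership labels are carried in `attr(, "membership")`.
#' @export
analyze_trajectory <- function(frames, cluster_cutoff = 1.0,
                               contact_cutoff = 0.5, sphere_radius = NULL,
                               mode = c("cluster", "contact"), csv = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(frames))
  rows <- vector("list", length(frames))
  membership <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    cfg <- frames[[f]]
    stopifnot(inherits(cfg, "molecular_configuration"))
    part <- cluster_molecules(cfg, cutoff = cluster_cutoff,
                              contact_cutoff = contact_cutoff)
    stats <- aggregate_stats(part)
    has_cnt <- length(cfg$walls) > 0
    fon <- if (has_cnt)
      fraction_on_cnt(cfg, part, contact_cutoff, mode) else NA_real_
    fin <- if (has_cnt && nrow(cfg$dox) > 0) {
      rings <- decompose_rings(cfg$walls[[1]])
      100 * count_inside(cfg, rings, sphere_radius)$count / nrow(cfg$dox)
    } else if (has_cnt) 0 else NA_real_
    rows[[f]] <- data.frame(
      time_ns = cfg$time_ns,
      n_aggregates = stats$n_aggregates,
      mean_aggregate_size = stats$mean_size,
      fraction_on_cnt = fon,
      fraction_inside_cnt = fin
    )
    membership[[f]] <- part$labels
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_ns = numeric(), n_aggregates = integer(),
               mean_aggregate_size = numeric(), fraction_on_cnt = numeric(),
               fraction_inside_cnt = numeric())
  rownames(out) <- NULL
  if (!is.null(csv))
    write.csv(out, csv, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  structure(out, membership = membership,
            class = c("aggregate_report", "data.frame"))
}
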