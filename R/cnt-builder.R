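## Ideal zigzag nanotube coordinate generator. A zigzag (n,0) tube is a
## graphene sheet wrapped so that the sheet circumference n*sqrt(3)*a_cc is
## preserved as arc length; the diameter is therefore exactly
## sqrt(3)*a_cc*n/pi. Wrapping preserves arcs, so nearest-neighbour chords
## are slightly shorter than the bond length a_cc (a curvature effect that
## vanishes as 1/n^2).
##
## Atoms come in crowns ("rings") of 2n atoms spanning two axial levels
## a_cc/2 apart; two rings per axial translational period of 3*a_cc, i.e.
## uniform ring-centroid spacing 1.5*a_cc. Ring indices are carried per atom
## so the interior-counting algorithm can reuse them directly.

#' Specify an ideal zigzag nanotube
#'
#' @param n zigzag chirality index (n,0); at least 8 (smaller radii
#'   self-intersect on wrapping).
#' @param length_nm tube length L (nm); the build truncates to whole rings.
#' @param a_cc carbon-carbon bond length (nm).
#' @param axis tube axis direction (unit 3-vector; normalized internally).
#'   Default along y, the long side of the reference simulation box.
#' @param origin axial start of the tube (nm).
#' @return An object of class `nanotube_spec` with the derived `diameter_nm`.
#' @examples
#' nanotube_spec(82)$diameter_nm   # 6.42 nm tube
#' @export
nanotube_spec <- function(n, length_nm = 20, a_cc = 0.142,
                          axis = c(0, 1, 0), origin = c(0, 0, 0)) {
  stopifnot(is.numeric(n), length(n) == 1)
  n <- as.integer(round(n))
  if (n < 8)
    stop("chirality index n must be >= 8 (the wrap self-intersects below)")
  stopifnot(length_nm > 0, a_cc > 0, length(axis) == 3, length(origin) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be a nonzero vector")
  structure(
    list(n = n, length_nm = length_nm, a_cc = a_cc,
         axis = axis / nrm, origin = as.numeric(origin),
         diameter_nm = sqrt(3) * a_cc * n / pi),
    class = "nanotube_spec"
  )
}

#' @export
print.nanotube_spec <- function(x, ...) {
  cat(sprintf("Zigzag (%d,0) nanotube: diameter %.3f nm, length %g nm\n",
              x$n, x$diameter_nm, x$length_nm))
  invisible(x)
}

## Orthonormal basis (e1, e2) perpendicular to unit axis u.
.axis_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Build the atomic coordinates of a zigzag nanotube wall
#'
#' Generates carbon positions on a cylinder of radius
#' `sqrt(3) * a_cc * n / (2 pi)` about the spec's axis. Rings of 2n atoms
#' are stacked with centroid spacing `1.5 * a_cc` (two rings per 3 a_cc
#' translational period); the build stops at the last whole ring covering
#' the requested length.
#'
#' @param spec a [nanotube_spec()].
#' @return A numeric matrix (atoms x 3, nm) of class `cnt_wall` with
#'   attributes `ring_index` (integer per atom), `n_rings`, `radius_nm`,
#'   and `spec`.
#' @export
build_zigzag <- function(spec) {
  stopifnot(inherits(spec, "nanotube_spec"))
  n <- spec$n; a <- spec$a_cc
  r <- sqrt(3) * a * n / (2 * pi)
  ring_pitch <- 1.5 * a
  n_rings <- max(1L, as.integer(ceiling(spec$length_nm / ring_pitch)))
  # Per ring k (1-based): two axial rows of n atoms, offset a/4 below/above
  # the ring centroid at z_k = (k - 1) * 1.5 a + a/4.
  k <- rep(seq_len(n_rings), each = 2 * n)
  within <- rep(seq_len(2 * n), times = n_rings) - 1L   # 0 .. 2n-1 per ring
  row_id <- within %/% n                                 # 0 = lower, 1 = upper
  j <- within %% n                                       # position around ring
  # Alternate the angular registry between consecutive rings so bonds tile
  # the honeycomb: odd rings have lower row at angle 2*pi*j/n, upper at
  # 2*pi*(j+1/2)/n; even rings are swapped.
  odd_ring <- (k %% 2L) == 1L
  half <- ifelse(odd_ring, row_id * 0.5, (1 - row_id) * 0.5)
  theta <- 2 * pi * (j + half) / n
  z <- (k - 1L) * ring_pitch + row_id * (a / 2)
  basis <- .axis_basis(spec$axis)
  xyz <- outer(r * cos(theta), basis$e1) +
         outer(r * sin(theta), basis$e2) +
         outer(z, spec$axis)
  xyz <- sweep(xyz, 2, spec$origin, "+")
  colnames(xyz) <- c("x", "y", "z")
  structure(xyz,
            ring_index = as.integer(k),
            n_rings = n_rings,
            radius_nm = r,
            spec = spec,
            class = c("cnt_wall", "matrix", "array"))
}

#' @export
print.cnt_wall <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Nanotube wall: %d atoms, %d rings, radius %.4f nm (n = %d)\n",
              nrow(x), attr(x, "n_rings"), attr(x, "radius_nm"), spec$n))
  invisible(x)
}

#' Build coaxial multi-wall nanotube coordinates
#'
#' For each requested diameter the zigzag index is chosen as
#' `round(pi * d / (sqrt(3) * a_cc))`, the closest realizable zigzag tube;
#' all walls share the axis and origin. Walls are returned innermost first.
#'
#' @param diameters_nm target wall diameters (nm), strictly increasing.
#' @param length_nm tube length (nm).
#' @param a_cc carbon-carbon bond length (nm).
#' @param axis,origin shared geometry, as in [nanotube_spec()].
#' @return A list of `cnt_wall` matrices (innermost first) of class
#'   `cnt_walls`.
#' @examples
#' walls <- build_mwcnt(c(6.42, 7.12, 7.83), length_nm = 2)
#' sapply(walls, function(w) attr(w, "spec")$n)   # 82 91 100
#' @export
build_mwcnt <- function(diameters_nm, length_nm = 20, a_cc = 0.142,
                        axis = c(0, 1, 0), origin = c(0, 0, 0)) {
  stopifnot(is.numeric(diameters_nm), length(diameters_nm) >= 1)
  if (any(diff(diameters_nm) <= 0))
    stop("wall diameters must be strictly increasing (innermost first)")
  walls <- lapply(diameters_nm, function(d) {
    n <- as.integer(round(pi * d / (sqrt(3) * a_cc)))
    build_zigzag(nanotube_spec(n, length_nm = length_nm, a_cc = a_cc,
                               axis = axis, origin = origin))
  })
  structure(walls, class = "cnt_walls")
}

#' @export
print.cnt_walls <- function(x, ...) {
  cat(sprintf("Multi-wall nanotube: %d coaxial wall(s)\n", length(x)))
  for (w in x) print(w)
  invisible(x)
}
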