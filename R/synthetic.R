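## Synthetic-data generators with exact ground truth: measurement series
## drawn from the isotherm/kinetic model forms with multiplicative lognormal
## noise, planted molecular configurations around a nanotube, and a toy
## sticky-aggregation dynamics. Every generator is bit-reproducible for a
## fixed seed.

#' Direct (non-linearized) isotherm model curves
#'
#' @param model `"freundlich"`, `"langmuir"` or `"temkin"`.
#' @param params named list/vector of model parameters (`kF`, `inv_n`;
#'   `qmax`, `KL`; `b`, `kT`).
#' @param ce equilibrium concentrations (mg mL-1).
#' @param temperature_k temperature (K), used by the Temkin curve.
#' @return qe values (mg g-1).
#' @export
isotherm_curve <- function(model, params, ce, temperature_k = 298.15) {
  p <- as.list(params)
  switch(match.arg(model, c("freundlich", "langmuir", "temkin")),
    freundlich = p$kF * ce^p$inv_n,
    langmuir = p$qmax * p$KL * ce / (1 + p$KL * ce),
    temkin = (R_GAS_KJ * temperature_k / p$b) * log(p$kT * ce)
  )
}

#' Integrated kinetic model curves
#'
#' Closed/integrated forms used for data generation: pseudo-first
#' `qt = qe (1 - exp(-k1 t))`, pseudo-second `qt = qe^2 k2 t/(1 + qe k2 t)`,
#' Elovich (simplified large-t form) `qt = (1/beta) ln(alpha beta t)`,
#' fractional power `qt = KFP t^v`, and the piecewise sqrt-t intra-particle
#' line (params `k1`, `C1`, `k2`, `C2`, `t_break`).
#'
#' @param model one of `"pseudo_first"`, `"pseudo_second"`, `"elovich"`,
#'   `"fractional_power"`, `"intraparticle"`.
#' @param params named list/vector of generating parameters.
#' @param t times (min).
#' @return qt values (mg g-1).
#' @export
kinetic_curve <- function(model, params, t) {
  p <- as.list(params)
  switch(match.arg(model, c("pseudo_first", "pseudo_second", "elovich",
                            "fractional_power", "intraparticle")),
    pseudo_first = p$qe * (1 - exp(-p$k1 * t)),
    pseudo_second = p$qe^2 * p$k2 * t / (1 + p$qe * p$k2 * t),
    elovich = (1 / p$beta) * log(p$alpha * p$beta * t),
    fractional_power = p$KFP * t^p$v,
    intraparticle = ifelse(t <= p$t_break,
                           p$k1 * sqrt(t) + p$C1,
                           p$k2 * sqrt(t) + p$C2)
  )
}

#' Generate a synthetic isotherm dataset with known ground truth
#'
#' Evaluates the chosen isotherm curve on a concentration grid and applies
#' multiplicative lognormal noise `exp(eps)`, `eps ~ N(0, noise_sd)`
#' (capacities stay positive). The default grid spans the measured
#' concentration window 0.067-0.533 mg mL-1.
#'
#' @inheritParams isotherm_curve
#' @param ce_grid concentration grid (mg mL-1).
#' @param noise_sd relative (lognormal) noise SD; 0 for noise-free data.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return An [isotherm_dataset()]; the generating model, parameters and
#'   noise level are attached as `attr(, "ground_truth")`.
#' @export
gen_isotherm <- function(model, params,
                         ce_grid = exp(seq(log(0.067), log(0.533),
                                           length.out = 20)),
                         noise_sd = 0.01, seed = NULL,
                         temperature_k = 298.15) {
  if (!is.null(seed)) set.seed(seed)
  qe <- isotherm_curve(model, params, ce_grid, temperature_k)
  if (any(qe <= 0))
    stop("generating parameters give non-positive qe on the grid")
  if (noise_sd > 0) qe <- qe * exp(rnorm(length(qe), 0, noise_sd))
  out <- isotherm_dataset(ce_grid, qe, temperature_k = temperature_k)
  attr(out, "ground_truth") <- list(model = model, params = as.list(params),
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic kinetics dataset with known ground truth
#'
#' Evaluates the integrated kinetic curve at the sampling times (default:
#' the twelve standard minutes) and applies multiplicative lognormal noise.
#'
#' @inheritParams kinetic_curve
#' @param t_points sampling times (min).
#' @param noise_sd relative (lognormal) noise SD.
#' @param seed RNG seed.
#' @param qe_exp experimental equilibrium capacity to attach (mg g-1);
#'   defaults to the generating `qe` when the model has one.
#' @return A [kinetic_dataset()] with `attr(, "ground_truth")`.
#' @export
gen_kinetics <- function(model, params, t_points = KINETIC_TIMES_MIN,
                         noise_sd = 0.01, seed = NULL, qe_exp = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qt <- kinetic_curve(model, params, t_points)
  if (any(qt < 0))
    stop("generating parameters give negative qt at the sampling times")
  if (noise_sd > 0) qt <- qt * exp(rnorm(length(qt), 0, noise_sd))
  if (is.null(qe_exp) && "qe" %in% names(as.list(params)))
    qe_exp <- as.list(params)$qe
  out <- kinetic_dataset(t_points, qt, qe_exp = qe_exp)
  attr(out, "ground_truth") <- list(model = model, params = as.list(params),
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Plant a molecular configuration with exact aggregate ground truth
#'
#' Places point-reduced molecules around (and inside) a nanotube so that
#' the aggregate structure is known by construction: `n_inside` molecules
#' in the inner channel hugging the innermost wall (within wall-contact
#' range and within the interior counting spheres), surface clusters docked
#' on the outer wall, and free clusters separated pairwise - and from the
#' tube - by more than `min_separation`. Within a cluster, members sit
#' within `intra_spacing` of the cluster seed so single-linkage keeps them
#' together.
#'
#' @param walls a `cnt_walls` list, a single `cnt_wall`, or a
#'   [nanotube_spec()] to build.
#' @param n_inside molecules planted in the inner channel.
#' @param surface_clusters integer vector of cluster sizes docked on the
#'   outer wall (e.g. `c(10, 10)`).
#' @param free_clusters integer vector of free-cluster sizes.
#' @param min_separation minimum distance (nm) between distinct planted
#'   groups; keep it at least twice the analysis linkage cutoff.
#' @param intra_spacing maximum member-to-seed distance within a cluster
#'   (nm); keep it below half the linkage cutoff.
#' @param box periodic box lengths (nm).
#' @param contact_gap radial gap (nm) between docked molecules and the wall
#'   they touch; must stay below the analysis contact cutoff.
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling attempts per free-cluster seat
#'   before the packing is declared infeasible.
#' @return A [molecular_configuration()] with `attr(, "ground_truth")`: a
#'   list holding `n_aggregates`, `mean_aggregate_size`, `fraction_on_cnt`,
#'   `fraction_inside_cnt` (percent), `membership` labels (tube aggregate
#'   = 1, free clusters 2, 3, ...), and `inside_ids`.
#' @export
plant_configuration <- function(walls, n_inside = 5,
                                surface_clusters = c(10, 10),
                                free_clusters = c(4, 4, 4),
                                min_separation = 2.0,
                                intra_spacing = 0.4,
                                box = c(20, 80, 20),
                                contact_gap = 0.35,
                                seed = NULL, max_attempts = 500) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(walls, "nanotube_spec")) walls <- list(build_zigzag(walls))
  if (inherits(walls, "cnt_wall")) walls <- list(walls)
  stopifnot(length(walls) >= 1)
  inner <- walls[[1]]; outer <- walls[[length(walls)]]
  spec <- attr(inner, "spec")
  if (is.null(spec)) stop("walls must come from build_zigzag()/build_mwcnt()")
  axis <- spec$axis
  basis <- .axis_basis(axis)
  r_in <- attr(inner, "radius_nm")
  r_out <- attr(outer, "radius_nm")
  L <- attr(inner, "n_rings") * 1.5 * spec$a_cc
  origin <- spec$origin
  cyl_point <- function(radius, axial, angle) {
    origin + axial * axis + radius * (cos(angle) * basis$e1 +
                                      sin(angle) * basis$e2)
  }
  pts <- list(); labels <- integer(0); inside_ids <- integer(0)
  # Interior molecules: radial seat r_in - contact_gap keeps them in wall
  # contact AND inside the 0.9*r_in counting spheres (contact_gap > 0.1*r_in
  # is required; checked).
  if (n_inside > 0) {
    if (contact_gap <= 0.1 * r_in + 0.02)
      stop("contact_gap too small: interior molecules would fall outside ",
           "the default counting spheres")
    ax_seats <- seq(0.15 * L, 0.85 * L, length.out = n_inside)
    ang <- runif(n_inside, 0, 2 * pi)
    for (i in seq_len(n_inside))
      pts[[length(pts) + 1L]] <- cyl_point(r_in - contact_gap,
                                           ax_seats[i], ang[i])
    labels <- c(labels, rep(1L, n_inside))
    inside_ids <- seq_len(n_inside)
  }
  # Surface clusters: seed docked at r_out + contact_gap, members within
  # intra_spacing of the seed (tangentially/axially, never closer to wall).
  for (sz in surface_clusters) {
    ax0 <- runif(1, 0.2 * L, 0.8 * L)
    an0 <- runif(1, 0, 2 * pi)
    seed_pt <- cyl_point(r_out + contact_gap, ax0, an0)
    pts[[length(pts) + 1L]] <- seed_pt
    if (sz > 1) {
      radial_dir <- cos(an0) * basis$e1 + sin(an0) * basis$e2
      for (jj in seq_len(sz - 1)) {
        off <- runif(3, -1, 1)
        off <- off / sqrt(sum(off^2)) * runif(1, 0.3, 1) * intra_spacing
        off <- off - min(0, sum(off * radial_dir)) * radial_dir  # stay outward
        pts[[length(pts) + 1L]] <- seed_pt + off
      }
    }
    labels <- c(labels, rep(1L, sz))
  }
  # Free clusters: rejection-sample seeds far from the tube surface and
  # from every previously placed group.
  n_free <- length(free_clusters)
  free_seeds <- list()
  tube_clear <- r_out + min_separation + intra_spacing
  for (ci in seq_len(n_free)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- runif(3, 0, 1) * box
      rel <- cand - origin
      rel <- rel - box * round(rel / box)     # nearest periodic image of tube
      axial <- sum(rel * axis)
      radial <- sqrt(max(sum(rel^2) - axial^2, 0))
      near_tube <- radial < tube_clear && axial > -min_separation &&
        axial < L + min_separation
      if (near_tube) next
      ok <- TRUE
      for (q in c(free_seeds, pts)) {
        if (min_image_distance(cand, q, box) <
            min_separation + 2 * intra_spacing) { ok <- FALSE; break }
      }
      if (ok) { free_seeds[[ci]] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("infeasible packing: could not seat free cluster ", ci,
           " after ", max_attempts, " attempts")
  }
  for (ci in seq_len(n_free)) {
    sz <- free_clusters[ci]
    pts[[length(pts) + 1L]] <- free_seeds[[ci]]
    if (sz > 1) {
      for (jj in seq_len(sz - 1)) {
        off <- runif(3, -1, 1)
        off <- off / sqrt(sum(off^2)) * runif(1, 0.3, 1) * intra_spacing
        pts[[length(pts) + 1L]] <- free_seeds[[ci]] + off
      }
    }
    labels <- c(labels, rep(1L + ci, sz))
  }
  dox <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 3)
  cfg <- molecular_configuration(dox, walls, box, time_ns = 0)
  n_mol <- nrow(dox)
  has_tube_agg <- (n_inside + sum(surface_clusters)) > 0
  n_agg <- as.integer(has_tube_agg) + n_free
  truth <- list(
    n_aggregates = n_agg,
    mean_aggregate_size = if (n_agg > 0) n_mol / n_agg else NA_real_,
    fraction_on_cnt = if (n_mol > 0)
      100 * (n_inside + sum(surface_clusters)) / n_mol else 0,
    fraction_inside_cnt = if (n_mol > 0) 100 * n_inside / n_mol else 0,
    membership = labels,
    inside_ids = inside_ids
  )
  attr(cfg, "ground_truth") <- truth
  cfg
}

#' Toy irreversible sticky-aggregation dynamics
#'
#' A qualitative stand-in for diffusion-limited molecular aggregation:
#' molecules start uniformly in the periodic box, every cluster takes an
#' independent Gaussian step per frame (rigid-body motion), and clusters
#' whose members come within `stick_cutoff` merge irreversibly. The number
#' of aggregates is therefore non-increasing and the molecule count is
#' conserved.
#'
#' @param n_molecules number of molecules.
#' @param box periodic box lengths (nm).
#' @param n_steps number of frames to simulate after the initial one.
#' @param step_sd per-frame Gaussian displacement SD (nm); 0 freezes the
#'   trajectory.
#' @param stick_cutoff merge distance (nm).
#' @param seed RNG seed.
#' @param dt_ns frame time spacing (ns), time-stamp metadata only.
#' @return List of [molecular_configuration()] frames (no nanotube), with
#'   `attr(, "cluster_history")`: integer vector of cluster counts per
#'   frame.
#' @export
toy_aggregation <- function(n_molecules, box = c(20, 80, 20), n_steps = 50,
                            step_sd = 0.3, stick_cutoff = 1.0, seed = NULL,
                            dt_ns = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_molecules >= 1, n_steps >= 0, step_sd >= 0, stick_cutoff > 0)
  pos <- cbind(runif(n_molecules, 0, box[1]),
               runif(n_molecules, 0, box[2]),
               runif(n_molecules, 0, box[3]))
  cluster <- seq_len(n_molecules)
  merge_contacts <- function() {
    repeat {
      merged <- FALSE
      ids <- unique(cluster)
      if (length(ids) <= 1) break
      for (i in seq_len(n_molecules)) {
        d2 <- .mi_dist2(pos[i, ], pos, box)
        hit <- which(d2 < stick_cutoff^2 & cluster != cluster[i])
        if (length(hit)) {
          cluster[cluster %in% cluster[hit]] <<- cluster[i]
          merged <- TRUE
        }
      }
      if (!merged) break
    }
  }
  merge_contacts()
  history <- integer(n_steps + 1)
  history[1] <- length(unique(cluster))
  frames <- vector("list", n_steps + 1)
  frames[[1]] <- molecular_configuration(pos, list(), box, time_ns = 0)
  for (s in seq_len(n_steps)) {
    ids <- unique(cluster)
    steps <- matrix(rnorm(3 * length(ids), 0, step_sd), ncol = 3)
    rownames(steps) <- as.character(ids)
    pos <- pos + steps[as.character(cluster), , drop = FALSE]
    pos <- pos %% matrix(box, n_molecules, 3, byrow = TRUE)
    merge_contacts()
    history[s + 1] <- length(unique(cluster))
    frames[[s + 1]] <- molecular_configuration(pos, list(), box,
                                               time_ns = s * dt_ns)
  }
  attr(frames, "cluster_history") <- history
  frames
}

#' Derive the reference molecule count from the 4:1 drug/tube mass ratio
#'
#' Number of point-reduced drug molecules matching a 4:1 drug-to-nanotube
#' mass ratio for a given set of walls, using the free-base molar mass
#' 543.52 g mol-1 for the drug and 12.011 g mol-1 per wall carbon.
#'
#' @param walls a `cnt_walls` list or single `cnt_wall`.
#' @param mass_ratio drug:tube mass ratio (default 4).
#' @param mw_drug drug molar mass (g mol-1); the free base by default.
#' @return Integer molecule count.
#' @export
dox_count_for_mass_ratio <- function(walls, mass_ratio = 4,
                                     mw_drug = 543.52) {
  if (inherits(walls, "cnt_wall")) walls <- list(walls)
  n_c <- sum(vapply(walls, nrow, integer(1)))
  as.integer(round(mass_ratio * n_c * 12.011 / mw_drug))
}
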