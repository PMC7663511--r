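# Aggregate clustering, adsorbed fraction, ring decomposition and interior
# counting, checked against brute-force oracles.

random_config <- function(n, box = c(12, 12, 12), walls = list(), seed) {
  set.seed(seed)
  pts <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  molecular_configuration(pts, walls, box, time_ns = 0)
}

test_that("two close molecules form one aggregate; far ones stay apart", {
  cfg <- molecular_configuration(rbind(c(1, 1, 1), c(1, 1, 1.5)),
                                 box = c(10, 10, 10))
  p <- cluster_molecules(cfg, cutoff = 1)
  expect_equal(p$n_aggregates, 1L)
  expect_equal(aggregate_stats(p)$mean_size, 2)
  # pairwise-distant molecules: N singleton aggregates
  cfg <- molecular_configuration(rbind(c(1, 1, 1), c(5, 5, 5), c(9, 1, 9)),
                                 box = c(20, 20, 20))
  p <- cluster_molecules(cfg, cutoff = 1)
  expect_equal(p$n_aggregates, 3L)
  expect_equal(aggregate_stats(p)$mean_size, 1)
})

test_that("clustering respects the minimum-image convention", {
  # molecules on opposite faces are wrapped neighbours
  cfg <- molecular_configuration(rbind(c(0.2, 5, 5), c(9.8, 5, 5)),
                                 box = c(10, 10, 10))
  expect_equal(cluster_molecules(cfg, cutoff = 0.5)$n_aggregates, 1L)
  expect_equal(min_image_distance(c(0.2, 5, 5), c(9.8, 5, 5),
                                  c(10, 10, 10)), 0.4)
})

test_that("empty configurations give empty partitions and reports", {
  cfg <- molecular_configuration(matrix(numeric(0), 0, 3),
                                 box = c(10, 10, 10))
  p <- cluster_molecules(cfg)
  expect_equal(p$n_aggregates, 0L)
  expect_length(p$labels, 0)
  expect_equal(nrow(analyze_trajectory(list())), 0)
})

test_that("partition equals BFS connected components on random configurations", {
  for (seed in 1:12) {
    cfg <- random_config(60, seed = seed)
    part <- cluster_molecules(cfg, cutoff = 1.5)
    D <- mi_dist_matrix(cfg$dox, cfg$box)
    adj <- D < 1.5
    diag(adj) <- FALSE
    oracle <- bfs_components(adj)
    expect_identical(canon_labels(part$labels), canon_labels(oracle))
    # labels form a true partition
    expect_equal(sum(part$sizes), nrow(cfg$dox))
    expect_setequal(unique(part$labels), seq_len(part$n_aggregates))
  }
})

test_that("aggregate counts are monotone in the linkage cutoff", {
  cfg <- random_config(50, seed = 99)
  cuts <- c(0.3, 0.6, 1.0, 1.5, 2.5, 4, 25)
  counts <- vapply(cuts, function(cc)
    cluster_molecules(cfg, cutoff = cc)$n_aggregates, integer(1))
  expect_true(all(diff(counts) <= 0))
  # limits: tiny cutoff isolates every molecule, huge cutoff joins all
  expect_equal(cluster_molecules(cfg, cutoff = 1e-6)$n_aggregates, 50L)
  expect_equal(counts[length(counts)], 1L)
})

test_that("aggregate_stats tallies sizes like an independent recount", {
  cfg <- random_config(80, seed = 5)
  part <- cluster_molecules(cfg, cutoff = 1.2)
  st <- aggregate_stats(part)
  recount <- table(part$labels)
  expect_equal(st$n_aggregates, length(recount))
  expect_equal(st$mean_size, mean(recount))
  # hand cases: {6} and {3,1}
  p1 <- structure(list(labels = rep(1L, 6), cnt_label = NA_integer_,
                       n_aggregates = 1L, sizes = 6L),
                  class = "aggregate_partition")
  expect_equal(aggregate_stats(p1), list(n_aggregates = 1L, mean_size = 6))
  p2 <- structure(list(labels = c(1L, 1L, 1L, 2L), cnt_label = NA_integer_,
                       n_aggregates = 2L, sizes = c(3L, 1L)),
                  class = "aggregate_partition")
  expect_equal(aggregate_stats(p2), list(n_aggregates = 2L, mean_size = 2))
})

test_that("adsorbed fraction agrees with a brute-force distance scan", {
  tube <- test_tube()
  box <- c(20, 80, 20)
  set.seed(17)
  n <- 40
  pts <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
               runif(n, 0, box[3]))
  cfg <- molecular_configuration(pts, list(tube), box)
  got <- fraction_on_cnt(cfg, contact_cutoff = 1.0, mode = "contact")
  # exhaustive pairwise scan
  hits <- 0
  for (i in seq_len(n)) {
    dmin <- Inf
    for (k in seq_len(nrow(tube))) {
      d <- pts[i, ] - tube[k, ]
      d <- d - box * round(d / box)
      dmin <- min(dmin, sqrt(sum(d^2)))
    }
    if (dmin < 1.0) hits <- hits + 1
  }
  expect_equal(got, 100 * hits / n)
  # fraction is monotone in the contact cutoff
  fr <- vapply(c(0.3, 0.6, 1, 2, 4), function(cc)
    fraction_on_cnt(cfg, contact_cutoff = cc, mode = "contact"), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("all-far and all-touching placements give 0% and 100%", {
  tube <- test_tube()
  far <- molecular_configuration(rbind(c(10, 70, 10), c(2, 65, 18)),
                                 list(tube), c(20, 80, 20))
  expect_equal(fraction_on_cnt(far, mode = "contact"), 0)
  expect_equal(fraction_on_cnt(far, cluster_molecules(far)), 0)
  r_out <- attr(tube, "radius_nm")
  touching <- molecular_configuration(
    rbind(c(10 + r_out + 0.3, 38, 10), c(10 - r_out - 0.3, 39, 10)),
    list(tube), c(20, 80, 20))
  expect_equal(fraction_on_cnt(touching, mode = "contact"), 100)
})

test_that("ring decomposition orders centroids on the axis and validates", {
  tube <- test_tube()
  rings <- decompose_rings(tube)
  expect_equal(nrow(rings$centroids), attr(tube, "n_rings"))
  spec <- attr(tube, "spec")
  rel <- sweep(rings$centroids, 2, spec$origin)
  axial <- drop(rel %*% spec$axis)
  expect_true(all(diff(axial) > 0))
  off <- sqrt(pmax(rowSums(rel^2) - axial^2, 0))
  expect_lt(max(off), 1e-6)
  # a generic (index-free) wall groups by axial coordinate...
  bare <- unclass(tube)[, , drop = FALSE]
  attr(bare, "ring_index") <- NULL
  rings2 <- decompose_rings(bare)
  expect_true(nrow(rings2$centroids) >= nrow(rings$centroids))
  # ...and a displaced atom breaks the uniform partition with a diagnostic
  bad <- bare
  bad[1, ] <- bad[1, ] + spec$axis * 5.03
  expect_error(decompose_rings(bad), "axial group")
})

test_that("interior counting matches the union-of-spheres oracle", {
  tube <- test_tube()
  rings <- decompose_rings(tube)
  box <- c(20, 80, 20)
  r_in <- attr(tube, "radius_nm")
  for (seed in 1:8) {
    set.seed(seed)
    # mix of points near the channel and far away
    n <- 60
    pts <- rbind(
      cbind(runif(n / 2, 8, 12), runif(n / 2, 36, 44), runif(n / 2, 8, 12)),
      cbind(runif(n / 2, 0, 20), runif(n / 2, 0, 80), runif(n / 2, 0, 20)))
    cfg <- molecular_configuration(pts, list(tube), box)
    got <- count_inside(cfg, rings, sphere_radius = 0.9 * r_in)
    oracle <- brute_inside(pts, rings$centroids, 0.9 * r_in, box)
    expect_identical(got$members, oracle)
    expect_equal(got$count, length(oracle))
  }
})

test_that("interior counting counts each molecule once and bounds the radius", {
  tube <- test_tube()
  rings <- decompose_rings(tube)
  # a molecule on the axis at mid-length sits in many overlapping spheres
  mid <- attr(tube, "spec")$origin + c(0, 2.5, 0)
  cfg <- molecular_configuration(rbind(mid), list(tube), c(20, 80, 20))
  got <- count_inside(cfg, rings)
  expect_equal(got$count, 1L)
  # radially outside the tube: never counted
  out <- molecular_configuration(rbind(mid + c(5, 0, 0)), list(tube),
                                 c(20, 80, 20))
  expect_equal(count_inside(out, rings)$count, 0L)
  expect_error(count_inside(cfg, rings, sphere_radius = 10),
               "sphere_radius")
})

test_that("analyze_trajectory is constant on a constant trajectory", {
  tube <- test_tube()
  cfg <- plant_configuration(tube, n_inside = 2, surface_clusters = 4,
                             free_clusters = c(3, 3), seed = 12)
  rep3 <- analyze_trajectory(list(cfg, cfg, cfg))
  expect_equal(nrow(rep3), 3)
  for (col in c("n_aggregates", "mean_aggregate_size", "fraction_on_cnt",
                "fraction_inside_cnt"))
    expect_equal(length(unique(rep3[[col]])), 1)
  # tidy CSV side-output
  p <- withr::local_tempfile(fileext = ".csv")
  analyze_trajectory(list(cfg), csv = p)
  expect_equal(nrow(read.csv(p)), 1)
})

test_that("XYZ round trip preserves configurations and wall grouping", {
  tube <- test_tube()
  cfg <- plant_configuration(tube, n_inside = 2, surface_clusters = 3,
                             free_clusters = 4, seed = 3)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cfg, p)
  back <- read_xyz(p)
  expect_length(back, 1)
  expect_equal(back[[1]]$dox, unname(cfg$dox), tolerance = 1e-8)
  expect_equal(nrow(back[[1]]$walls[[1]]), nrow(tube))
  expect_equal(attr(back[[1]]$walls[[1]], "ring_index"),
               attr(tube, "ring_index"))
  expect_equal(back[[1]]$box, cfg$box)
  # metrics computed on the reread frame match the original
  expect_equal(as.data.frame(analyze_trajectory(back)),
               as.data.frame(analyze_trajectory(list(cfg))),
               tolerance = 1e-7)
})
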