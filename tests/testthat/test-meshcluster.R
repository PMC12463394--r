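# Surface meshing, geodesics and geodesic DBSCAN.

test_that("planar clouds yield an interpolating planar mesh", {
  g <- seq(0, 120, by = 10)
  pts <- cbind(x = 0, y = rep(g, times = length(g)), z = rep(g, each = length(g)))
  m <- build_mesh(pts, target_faces = 10000)
  expect_equal(nrow(m$vertices), nrow(pts))
  expect_lt(max(abs(m$vertices[, "x"])), 1e-12)
  expect_equal(mesh_area(m), 120^2, tolerance = 1e-9)
  expect_error(build_mesh(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               class = "synquant_geometry_error")
})

test_that("sphere clouds mesh as closed surfaces with the right area", {
  set.seed(41)
  u <- matrix(rnorm(3 * 2000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 200
  m <- build_mesh(u, target_faces = 10000)
  expect_lt(abs(mesh_area(m) - 4 * pi * 200^2) / (4 * pi * 200^2), 0.05)
  expect_equal(euler_characteristic(m), 2L)
  # simplification preserves the closed topology
  m2 <- build_mesh(u, target_faces = 1200)
  expect_lte(nrow(m2$faces), 1200)
  expect_equal(euler_characteristic(m2), 2L)
})

test_that("receptors project to their nearest vertex deterministically", {
  g <- seq(0, 100, by = 10)
  pts <- cbind(x = 0, y = rep(g, times = length(g)), z = rep(g, each = length(g)))
  m <- build_mesh(pts)
  on_vertex <- project_receptors(matrix(c(0, 50, 50), 1), m)
  expect_equal(m$vertices[on_vertex$projected_vertex, ],
               c(x = 0, y = 50, z = 50))
  expect_equal(on_vertex$projection_residual, 0)
  # an ectodomain-height receptor 14 nm off the surface
  off <- project_receptors(matrix(c(14, 50, 50), 1), m)
  expect_equal(m$vertices[off$projected_vertex, c("y", "z")],
               c(y = 50, z = 50))
  expect_equal(off$projection_residual, 14)
  # brute-force agreement on random queries
  set.seed(5)
  q <- cbind(runif(100, -5, 5), runif(100, 0, 100), runif(100, 0, 100))
  rs <- project_receptors(q, m)
  D <- outer(rowSums(q^2), rowSums(m$vertices^2), "+") -
    2 * q %*% t(m$vertices)
  expect_equal(rs$projected_vertex, apply(D, 1, which.min))
})

test_that("geodesics equal a Floyd-Warshall oracle and bound Euclidean", {
  # hand case: 3 collinear vertices spaced 5 nm in a path
  path3 <- surface_mesh(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0), c(5, 4, 0)),
                        rbind(c(1, 2, 4), c(2, 3, 4)))
  d <- geodesic_matrix(path3, 1:3)
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d[1, 3], 10)

  set.seed(17)
  for (i in 1:5) {
    n <- sample(40:120, 1)
    pts <- cbind(0.5 * rnorm(n), matrix(runif(2 * n, 0, 80), ncol = 2))
    colnames(pts) <- c("x", "y", "z")
    m <- build_mesh(pts)
    ed <- mesh_edges(m)
    oracle <- floyd_warshall_oracle(nrow(m$vertices), ed$from, ed$to, ed$length)
    ids <- sort(sample(nrow(m$vertices), 12))
    got <- geodesic_matrix(m, ids)
    expect_equal(got, oracle[ids, ids], tolerance = 1e-12)
    # metric lower bound
    euc <- as.matrix(dist(m$vertices[ids, ]))
    expect_true(all(got >= euc - 1e-9))
  }
  expect_error(geodesic_matrix(path3, integer(0)),
               class = "synquant_input_error")
})

test_that("halving the mesh edge length barely changes sphere geodesics", {
  set.seed(23)
  u <- matrix(rnorm(3 * 8000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 150
  # six fixed, well-separated surface points (octahedral directions)
  anchors <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * 150
  geo_between <- function(target_faces) {
    m <- build_mesh(u, target_faces = target_faces)
    ids <- project_receptors(anchors, m)$projected_vertex
    geodesic_matrix(m, ids)
  }
  coarse <- geo_between(1000)   # 4x fewer faces = ~2x longer edges
  fine <- geo_between(4000)
  off <- (abs(coarse - fine) / pmax(fine, 1))[upper.tri(fine)]
  # edge-graph geodesics carry a path-dependent stretch of a few percent;
  # the aggregate converges under refinement while single pairs wobble more
  expect_lt(mean(off), 0.05)
  expect_lt(max(off), 0.15)
})

test_that("DBSCAN on the precomputed metric matches its definition", {
  # 3 mutually close receptors stay noise below the minimum size
  d3 <- as.matrix(dist(rbind(c(0, 0), c(10, 0), c(5, 8.6))))
  expect_equal(cluster_receptors(d3, eps = 70, min_size = 4), rep(-1L, 3))

  # two groups of 6 on a plane, far apart: 2 clusters, oracle-identical
  set.seed(9)
  pts <- rbind(cbind(runif(6, 0, 20), runif(6, 0, 20)),
               cbind(runif(6, 300, 320), runif(6, 300, 320)))
  D <- as.matrix(dist(pts))
  lab <- cluster_receptors(D, eps = 70, min_size = 4)
  expect_equal(lab, dbscan_oracle(D, 70, 4))
  expect_equal(sort(unique(lab)), c(1L, 2L))
  expect_equal(as.integer(table(lab)), c(6L, 6L))

  # Inf entries are never neighbours
  D2 <- D
  D2[1:6, 7:12] <- Inf
  D2[7:12, 1:6] <- Inf
  expect_equal(cluster_receptors(D2, eps = 1e6, min_size = 4),
               rep(c(1L, 2L), each = 6))

  bad <- D
  bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(cluster_receptors(bad, 70, 4), class = "synquant_input_error")
})

test_that("geodesic labels match Euclidean DBSCAN on a flat sheet", {
  set.seed(77)
  for (i in 1:3) {
    sc <- make_synapse_scene("plane", extent = 600, spacing = 15,
                             n_clusters = 3, receptors_per_cluster = 7,
                             cluster_sigma = 15, guard_distance = 220,
                             seed = 300 + i)
    rep_ <- analyse_receptor_clusters(sc$posm, sc$receptors,
                                      target_faces = 4000)
    euc <- as.matrix(dist(as.matrix(sc$receptors[, c("x", "y", "z")])))
    expect_equal(rep_$labels, dbscan_oracle(euc, 70, 4))
  }
})

test_that("a fold separates groups geodesically but not in Euclidean space", {
  # hairpin sheet: two flat 200 nm strips 30 nm apart, joined by a
  # semicircular bend
  gap <- 30
  f <- function(s, w) {
    if (s <= 200) c(0, s, w)
    else if (s <= 200 + pi * gap / 2) {
      a <- (s - 200) / (gap / 2)
      c(gap / 2 - cos(a) * gap / 2, 200 + sin(a) * gap / 2, w)
    } else c(gap, 200 - (s - 200 - pi * gap / 2), w)
  }
  L <- 2 * 200 + pi * gap / 2
  m <- strip_mesh(f, seq(0, L, by = 5), seq(0, 60, by = 5))
  # two groups of 5 receptors facing each other across the fold
  g1 <- cbind(0, seq(20, 60, 10), 30)
  g2 <- cbind(gap, seq(20, 60, 10), 30)
  rs <- project_receptors(rbind(g1, g2), m)
  geo <- geodesic_matrix(m, rs$projected_vertex)
  euc <- as.matrix(dist(rbind(g1, g2)))
  # Euclidean: one cluster (gap 30 < 70); geodesic: two (path goes round)
  expect_equal(length(unique(dbscan_oracle(euc, 70, 4))), 1L)
  lab_geo <- cluster_receptors(geo, eps = 70, min_size = 4)
  expect_equal(sort(unique(lab_geo)), c(1L, 2L))
  expect_gt(min(geo[1:5, 6:10]), 70)
})

test_that("clusters are classed by cleft membership of their members", {
  zone <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  rset <- structure(list(projected_vertex = 1:6,
                         projection_residual = rep(0, 6)),
                    class = "receptor_set")
  all_in <- classify_clusters(rep(1L, 6), rset, rep(TRUE, 6))
  expect_equal(all_in$clusters$location_class, "cleft")
  none_in <- classify_clusters(rep(1L, 6), rset, rep(FALSE, 6))
  expect_equal(none_in$clusters$location_class, "perisynaptic")
  mixed <- classify_clusters(c(1L, 1L, 1L, 1L, 1L, -1L), rset, zone)
  expect_equal(mixed$clusters$location_class, "boundary")
  expect_equal(mixed$n_noise, 1L)
  expect_error(classify_clusters(1:3, rset, zone),
               class = "synquant_consistency_error")
})

test_that("cluster location classes recover the scene construction", {
  sc <- make_synapse_scene("plane", separation = 30, extent = 900,
                           spacing = 20, presm_extent = 450,
                           n_clusters = 3, receptors_per_cluster = 8,
                           cluster_sigma = 12, guard_distance = 260,
                           seed = 11)
  cm <- cleft_distances(sc$presm, sc$posm)
  zone <- cleft_zone(sc$posm, cm)
  rep_ <- analyse_receptor_clusters(sc$posm, sc$receptors, in_cleft = zone,
                                    target_faces = 5000)
  expect_equal(rep_$n_clusters, 3L)
  # every receptor well inside the PreSM footprint must be in a cleft or
  # boundary cluster; classes are all from the fixed vocabulary
  expect_true(all(rep_$clusters$location_class %in%
                    c("cleft", "boundary", "perisynaptic")))
})
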