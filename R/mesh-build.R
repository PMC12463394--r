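# Surface reconstruction from segmented membrane point clouds.
#
# Two reconstruction paths cover the surface families the pipeline meets:
#   * sheet-like clouds (planes, gently undulating membranes): points are
#     projected onto their principal plane and triangulated by a 2D Delaunay
#     (Bowyer-Watson); faces are lifted back to the original 3D points, so
#     the mesh interpolates the samples exactly.
#   * spherical clouds: stereographic projection from one sample point,
#     Delaunay of the projection, then closing the hole with a fan to the
#     pole -- the classical construction of the convex-hull triangulation of
#     points on a sphere, giving a closed mesh (Euler characteristic 2).
# Simplification to a face budget is done by deterministic farthest-point
# subsampling followed by re-triangulation, which preserves the surface
# topology by construction.

#' 2D Delaunay triangulation (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation with a vectorised in-circumcircle
#' test. A deterministic sub-nanometre jitter is applied internally to break
#' cocircular ties (regular grids); returned triangles index the original,
#' unjittered points.
#'
#' @param xy numeric matrix (n x 2), n >= 3.
#' @return list with `triangles` (m x 3 integer, counter-clockwise) and
#'   `boundary` (k x 2 integer edges of the outer hull).
#' @export
delaunay2d <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3L) stop_synquant("need >= 3 points", "synquant_geometry_error")
  rng <- apply(xy, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-9)
  # deterministic tie-breaking jitter, hash-based so it is seed-independent
  h1 <- ((seq_len(n) * 2654435761) %% 104729) / 104729 - 0.5
  h2 <- ((seq_len(n) * 40503 + 17) %% 104729) / 104729 - 0.5
  pts <- xy + span * 1e-7 * cbind(h1, h2)
  ctr <- colMeans(pts)
  big <- span * 50
  sv <- rbind(ctr + c(0, 2.3 * big), ctr + c(-2 * big, -1.2 * big),
              ctr + c(2 * big, -1.2 * big))
  P <- rbind(pts, sv)
  si <- n + 1:3
  circum <- function(ia, ib, ic) {
    a <- P[ia, , drop = FALSE]; b <- P[ib, , drop = FALSE]
    c2 <- P[ic, , drop = FALSE]
    d <- 2 * (a[, 1] * (b[, 2] - c2[, 2]) + b[, 1] * (c2[, 2] - a[, 2]) +
                c2[, 1] * (a[, 2] - b[, 2]))
    d[abs(d) < 1e-300] <- 1e-300
    as2 <- rowSums(a^2); bs2 <- rowSums(b^2); cs2 <- rowSums(c2^2)
    ux <- (as2 * (b[, 2] - c2[, 2]) + bs2 * (c2[, 2] - a[, 2]) +
             cs2 * (a[, 2] - b[, 2])) / d
    uy <- (as2 * (c2[, 1] - b[, 1]) + bs2 * (a[, 1] - c2[, 1]) +
             cs2 * (b[, 1] - a[, 1])) / d
    list(cx = ux, cy = uy, r2 = (ux - a[, 1])^2 + (uy - a[, 2])^2)
  }
  tri <- matrix(si, ncol = 3)
  cc <- circum(tri[, 1], tri[, 2], tri[, 3])
  ccx <- cc$cx; ccy <- cc$cy; r2 <- cc$r2
  enc <- as.double(n + 4L)
  for (p in seq_len(n)) {
    px <- pts[p, 1]; py <- pts[p, 2]
    bad <- which((px - ccx)^2 + (py - ccy)^2 < r2 * (1 + 1e-12))
    bt <- tri[bad, , drop = FALSE]
    e1 <- rbind(bt[, 1:2], bt[, 2:3], bt[, c(3, 1)])
    lo <- pmin(e1[, 1], e1[, 2]); hi <- pmax(e1[, 1], e1[, 2])
    key <- lo * enc + hi
    cnt <- table(key)
    once <- as.double(names(cnt)[cnt == 1L])
    keep_edge <- key %in% once
    be <- e1[keep_edge, , drop = FALSE]   # boundary edges keep winding
    new_tri <- cbind(be, p)
    ncc <- circum(new_tri[, 1], new_tri[, 2], new_tri[, 3])
    keep <- setdiff(seq_len(nrow(tri)), bad)
    tri <- rbind(tri[keep, , drop = FALSE], new_tri)
    ccx <- c(ccx[keep], ncc$cx); ccy <- c(ccy[keep], ncc$cy)
    r2 <- c(r2[keep], ncc$r2)
  }
  real <- rowSums(matrix(tri %in% si, ncol = 3)) == 0L
  tri <- tri[real, , drop = FALSE]
  storage.mode(tri) <- "integer"
  # outer boundary = edges used by exactly one remaining triangle
  e1 <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- pmin(e1[, 1], e1[, 2]) * enc + pmax(e1[, 1], e1[, 2])
  cnt <- table(key)
  once <- as.double(names(cnt)[cnt == 1L])
  boundary <- e1[key %in% once, , drop = FALSE]
  list(triangles = tri, boundary = boundary)
}

fit_sphere <- function(pts) {
  # algebraic least squares: |x|^2 = 2 c.x + k
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  centre <- sol[1:3]
  r <- sqrt(max(sol[4] + sum(centre^2), 0))
  resid <- sqrt(rowSums(sweep(pts, 2, centre)^2)) - r
  list(centre = centre, radius = r, rms = sqrt(mean(resid^2)))
}

farthest_point_sample <- function(pts, k) {
  n <- nrow(pts)
  if (k >= n) return(seq_len(n))
  sel <- integer(k)
  d0 <- rowSums(sweep(pts, 2, colMeans(pts))^2)
  sel[1] <- which.max(d0)
  mind <- rowSums(sweep(pts, 2, pts[sel[1], ])^2)
  for (i in 2:k) {
    sel[i] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(pts, 2, pts[sel[i], ])^2))
  }
  sort(sel)
}

#' Reconstruct a membrane surface mesh from segmented points
#'
#' Builds an interpolating triangle mesh over a segmented membrane point
#' cloud and, when the triangulation would exceed `target_faces`, simplifies
#' it by farthest-point subsampling and re-triangulation (topology is
#' preserved by construction). Sheet-like clouds are triangulated in their
#' principal plane; clouds lying on a sphere are triangulated as a closed
#' surface.
#'
#' @param points a [point_table] or n x 3 matrix (nm).
#' @param target_faces maximum face count after simplification.
#' @return a [surface_mesh] whose vertices are a subset of the input points.
#' @export
build_mesh <- function(points, target_faces = 10000L) {
  pts <- as_xyz(points)
  if (nrow(pts) < 3L) {
    stop_synquant("need >= 3 points to mesh", "synquant_geometry_error")
  }
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0)
  if (sv$d[2] / max(sv$d[1], 1e-12) < 1e-8) {
    stop_synquant("degenerate (collinear) point cloud", "synquant_geometry_error")
  }
  spherical <- FALSE
  sph <- NULL
  if (sv$d[3] / sv$d[1] > 0.05) {
    sph <- tryCatch(fit_sphere(pts), error = function(e) NULL)
    if (!is.null(sph) && sph$radius > 0 && sph$rms / sph$radius < 0.05) {
      spherical <- TRUE
    }
  }
  # a triangulation of n surface samples has ~2n faces; subsample to budget
  n_keep <- max(4L, min(nrow(pts), as.integer(ceiling(target_faces / 2)) + 2L))
  idx <- if (n_keep < nrow(pts)) farthest_point_sample(pts, n_keep)
         else seq_len(nrow(pts))
  p <- pts[idx, , drop = FALSE]
  if (spherical) {
    mesh <- mesh_sphere_path(p, sph)
  } else {
    uv <- sweep(p, 2, ctr) %*% sv$v[, 1:2]
    dt <- delaunay2d(uv)
    mesh <- surface_mesh(p, dt$triangles)
  }
  mesh
}

mesh_sphere_path <- function(p, sph) {
  n <- nrow(p)
  centred <- sweep(p, 2, sph$centre)
  rad <- sqrt(rowSums(centred^2))
  unit <- centred / rad
  # pole = the sample most isolated from its nearest neighbour, which bounds
  # the stereographic blow-up near the pole
  sub <- if (n > 600L) unique(as.integer(round(seq(1L, n, length.out = 600L))))
         else seq_len(n)
  pole <- 1L
  best <- -Inf
  d_to_all <- function(i) sqrt(rowSums(sweep(p, 2, p[i, ])^2))
  for (i in sub) {
    d <- d_to_all(i); d[i] <- Inf
    if (min(d) > best) { best <- min(d); pole <- i }
  }
  np <- unit[pole, ]
  # tangent basis at the pole
  a <- if (abs(np[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * np) * np; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(np[2] * e1[3] - np[3] * e1[2],
          np[3] * e1[1] - np[1] * e1[3],
          np[1] * e1[2] - np[2] * e1[1])
  others <- setdiff(seq_len(n), pole)
  u <- unit[others, , drop = FALSE]
  zeta <- u %*% np
  denom <- pmax(1 - as.numeric(zeta), 1e-9)
  uv <- cbind(u %*% e1, u %*% e2) / denom
  dt <- delaunay2d(uv)
  tri <- matrix(others[dt$triangles], ncol = 3)
  fan <- cbind(matrix(others[dt$boundary], ncol = 2), pole)
  surface_mesh(p, rbind(tri, fan))
}

#' Unique undirected edges of a mesh with Euclidean lengths
#'
#' @param mesh a [surface_mesh].
#' @return data.frame with columns `from`, `to`, `length` (nm).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- !duplicated(lo * (nrow(mesh$vertices) + 1) + hi)
  lo <- lo[key]; hi <- hi[key]
  len <- sqrt(rowSums((mesh$vertices[lo, , drop = FALSE] -
                         mesh$vertices[hi, , drop = FALSE])^2))
  data.frame(from = lo, to = hi, length = len)
}

#' Total surface area of a triangle mesh
#' @param mesh a [surface_mesh].
#' @return area in nm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a [surface_mesh].
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

mesh_igraph <- function(mesh) {
  ed <- mesh_edges(mesh)
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$from, ed$to))
  igraph::E(g)$weight <- ed$length
  g
}
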