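# Geodesic DBSCAN clustering of receptors on a membrane mesh.
#
# Receptor positions (membrane-insertion points, possibly displaced off the
# surface by segmentation noise or the ~14 nm ectodomain) are projected to
# their nearest mesh vertex; pairwise distances are shortest paths along the
# edge-weighted mesh graph (Dijkstra); DBSCAN runs on that precomputed
# metric with the field-standard parameters eps = 70 nm, minimum cluster
# size 4. Clusters are then classed by where their members sit relative to
# the synaptic cleft: all members in-cleft -> "cleft", none -> "perisynaptic",
# otherwise "boundary".

#' Project receptor positions to their nearest mesh vertex
#'
#' Exhaustive nearest-vertex assignment (ties broken by lowest vertex index)
#' with the Euclidean residual recorded per receptor.
#'
#' @param receptors n x 3 matrix or [point_table] of receptor positions (nm).
#' @param mesh a [surface_mesh].
#' @return a `receptor_set`: list with `positions`, `projected_vertex`,
#'   `projection_residual`.
#' @export
project_receptors <- function(receptors, mesh) {
  pos <- as_xyz(receptors)
  if (nrow(mesh$vertices) == 0L) {
    stop_synquant("mesh has no vertices", "synquant_input_error")
  }
  nn <- nearest_neighbours(pos, mesh$vertices)
  structure(list(positions = pos,
                 projected_vertex = nn$index,
                 projection_residual = nn$distance),
            class = "receptor_set")
}

#' Geodesic distance matrix between mesh vertices
#'
#' Shortest-path lengths along the edge graph of the mesh (edge weight =
#' Euclidean edge length), computed with Dijkstra's algorithm. Vertex pairs
#' in different mesh components get `Inf`.
#'
#' @param mesh a [surface_mesh].
#' @param vertex_ids integer vertex indices.
#' @return symmetric numeric matrix (nm) with zero diagonal.
#' @export
geodesic_matrix <- function(mesh, vertex_ids) {
  vertex_ids <- as.integer(vertex_ids)
  if (length(vertex_ids) == 0L) {
    stop_synquant("vertex_ids is empty", "synquant_input_error")
  }
  if (any(vertex_ids < 1L | vertex_ids > nrow(mesh$vertices))) {
    stop_synquant("vertex_ids out of range", "synquant_input_error")
  }
  g <- mesh_igraph(mesh)
  uq <- unique(vertex_ids)
  du <- igraph::distances(g, v = uq, to = uq, algorithm = "dijkstra")
  pos <- match(vertex_ids, uq)
  d <- du[pos, pos, drop = FALSE]
  dimnames(d) <- NULL
  # symmetrise away last-bit asymmetries from independent source runs
  (d + t(d)) / 2
}

#' DBSCAN on a precomputed distance matrix
#'
#' Standard DBSCAN (queue-based region expansion) on a precomputed,
#' symmetric distance matrix. The eps-neighbourhood of a point includes the
#' point itself, so a point is core when at least `min_size` points
#' (including itself) lie within `eps`. `Inf` entries never count as
#' neighbours. Labels are deterministic given the row order: clusters are
#' numbered by their first (lowest-index) core point.
#'
#' @param distances square symmetric matrix with zero diagonal (nm).
#' @param eps neighbourhood radius (nm); field default 70.
#' @param min_size minimum cluster size; field default 4.
#' @return integer label vector; -1 marks noise.
#' @export
cluster_receptors <- function(distances, eps = 70, min_size = 4L) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d)) {
    stop_synquant("distance matrix must be square", "synquant_input_error")
  }
  fin <- is.finite(d) & is.finite(t(d))
  if (max(abs(d[fin] - t(d)[fin]), 0) > 1e-9 ||
      any(is.finite(d) != is.finite(t(d)))) {
    stop_synquant("distance matrix must be symmetric", "synquant_input_error")
  }
  if (eps <= 0 || min_size < 1L) {
    stop_synquant("eps must be > 0 and min_size >= 1", "synquant_input_error")
  }
  n <- nrow(d)
  labels <- rep(-1L, n)
  if (n == 0L) return(labels)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_size
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == -1L) labels[k] <- cl
        if (core[k] && !visited[k]) {
          visited[k] <- TRUE
          labels[k] <- cl
          queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Transfer an in-cleft mask from membrane points to mesh vertices
#'
#' The cleft zone is defined on the segmented PoSM points (see
#' [cleft_zone()]); each mesh vertex inherits the flag of its nearest PoSM
#' point.
#'
#' @param mesh a [surface_mesh] built from the PoSM points.
#' @param posm a [point_table] of PoSM points (nm).
#' @param in_cleft logical vector, one flag per PoSM point.
#' @return logical vector, one flag per mesh vertex.
#' @export
vertex_cleft_zone <- function(mesh, posm, in_cleft) {
  pos <- as_xyz(posm)
  if (length(in_cleft) != nrow(pos)) {
    stop_synquant("in_cleft length must match PoSM point count",
                  "synquant_consistency_error")
  }
  nn <- nearest_neighbours(mesh$vertices, pos)
  as.logical(in_cleft[nn$index])
}

#' Classify receptor clusters by cleft location
#'
#' Builds the per-synapse cluster report: cluster sizes, members and a
#' location class per cluster -- `"cleft"` when every member projects to an
#' in-cleft vertex, `"perisynaptic"` when none does, `"boundary"` otherwise.
#'
#' @param labels integer cluster labels from [cluster_receptors()] (-1 noise).
#' @param receptorset a `receptor_set` from [project_receptors()].
#' @param vertex_in_cleft logical per mesh vertex (see [vertex_cleft_zone()]).
#' @return a `cluster_report`: list with `labels`, per-cluster data.frame
#'   `clusters` (label, size, location_class), `members` list, and summary
#'   counts `n_clusters`, `n_noise`, `class_counts`.
#' @export
classify_clusters <- function(labels, receptorset, vertex_in_cleft) {
  if (length(labels) != length(receptorset$projected_vertex)) {
    stop_synquant("labels and receptor set differ in length",
                  "synquant_consistency_error")
  }
  member_cleft <- as.logical(vertex_in_cleft[receptorset$projected_vertex])
  ids <- sort(unique(labels[labels > 0L]))
  members <- lapply(ids, function(l) which(labels == l))
  cls <- vapply(members, function(m) {
    inn <- member_cleft[m]
    if (all(inn)) "cleft" else if (!any(inn)) "perisynaptic" else "boundary"
  }, character(1))
  clusters <- data.frame(label = ids,
                         size = vapply(members, length, 1L),
                         location_class = if (length(ids)) cls else character(0))
  structure(list(
    labels = labels,
    clusters = clusters,
    members = members,
    n_clusters = length(ids),
    n_noise = sum(labels == -1L),
    class_counts = c(cleft = sum(cls == "cleft"),
                     boundary = sum(cls == "boundary"),
                     perisynaptic = sum(cls == "perisynaptic"))
  ), class = "cluster_report")
}

#' Run the full receptor-cluster analysis for one synapse
#'
#' Convenience wrapper: mesh the PoSM points, project receptors, compute the
#' geodesic matrix between their projections, cluster with DBSCAN and class
#' each cluster against the cleft zone.
#'
#' @param posm PoSM [point_table] (nm).
#' @param receptors receptor positions (nm).
#' @param in_cleft logical per PoSM point (from [cleft_zone()]); defaults to
#'   all `TRUE` (whole membrane treated as cleft).
#' @param eps,min_size DBSCAN parameters (nm, count).
#' @param target_faces mesh simplification budget.
#' @return a `cluster_report` with the mesh and receptor set attached.
#' @export
analyse_receptor_clusters <- function(posm, receptors,
                                      in_cleft = NULL,
                                      eps = 70, min_size = 4L,
                                      target_faces = 10000L) {
  mesh <- build_mesh(posm, target_faces = target_faces)
  rset <- project_receptors(receptors, mesh)
  if (is.null(in_cleft)) in_cleft <- rep(TRUE, nrow(as.data.frame(posm)))
  vz <- vertex_cleft_zone(mesh, posm, in_cleft)
  dm <- geodesic_matrix(mesh, rset$projected_vertex)
  labels <- cluster_receptors(dm, eps = eps, min_size = min_size)
  rep_ <- classify_clusters(labels, rset, vz)
  rep_$mesh <- mesh
  rep_$receptors <- rset
  rep_
}
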