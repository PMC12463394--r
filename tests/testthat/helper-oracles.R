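# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementations.

# Welch two-sample t statistic and two-sided p, written out from the formula
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, p = 2 * pt(-abs(t), df = df), df = df)
}

# vectorised Floyd-Warshall all-pairs shortest paths from an edge list
floyd_warshall_oracle <- function(n, from, to, w) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_along(from)) {
    D[from[i], to[i]] <- min(D[from[i], to[i]], w[i])
    D[to[i], from[i]] <- D[from[i], to[i]]
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# DBSCAN oracle: connected components of the mutual-eps graph restricted to
# core points, then border points attach to the first core neighbour's
# cluster. Neighbourhoods include the point itself.
dbscan_oracle <- function(d, eps, min_size) {
  n <- nrow(d)
  adj <- d <= eps
  core <- rowSums(adj) >= min_size
  labels <- rep(-1L, n)
  cl <- 0L
  comp <- rep(NA_integer_, n)
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cl <- cl + 1L
    frontier <- i
    comp[i] <- cl
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(j) {
        which(adj[j, ] & core & is.na(comp))
      })))
      comp[nxt] <- cl
      frontier <- nxt
    }
  }
  labels[core] <- comp[core]
  for (i in which(!core)) {
    nb_core <- which(adj[i, ] & core)
    if (length(nb_core)) labels[i] <- comp[nb_core[1]]
  }
  labels
}

# adjusted-for-nothing plain Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}

# regular grid strip mesh over a parametrised surface f(s, w) -> xyz;
# used to build folded sheets without going through build_mesh
strip_mesh <- function(f, s_vals, w_vals) {
  ns <- length(s_vals); nw <- length(w_vals)
  vtx <- do.call(rbind, lapply(seq_len(ns), function(i) {
    t(vapply(seq_len(nw), function(j) f(s_vals[i], w_vals[j]), numeric(3)))
  }))
  id <- function(i, j) (i - 1L) * nw + j
  faces <- do.call(rbind, lapply(seq_len(ns - 1L), function(i) {
    do.call(rbind, lapply(seq_len(nw - 1L), function(j) {
      rbind(c(id(i, j), id(i + 1L, j), id(i, j + 1L)),
            c(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L)))
    }))
  }))
  surface_mesh(vtx, faces)
}
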