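#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed without
#' disturbing the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# coerce a point_table, data.frame or bare n x 3 matrix to an xyz matrix
as_xyz <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) {
      stop_synquant("expected 3 coordinate columns", "synquant_input_error")
    }
    colnames(x) <- c("x", "y", "z")
    return(x)
  }
  df <- as.data.frame(x)
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop_synquant("expected columns x, y, z", "synquant_input_error")
  }
  as.matrix(df[, c("x", "y", "z")])
}

stop_synquant <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "synquant_error")))
}

#' Chunked exact nearest-neighbour search between two point sets
#'
#' For each row of `query` finds the index of the closest row of `ref`
#' (Euclidean distance). Exhaustive and exact; computed in row blocks so the
#' full distance matrix is never materialised. Ties are broken by the lowest
#' reference index.
#'
#' @param query numeric matrix, one point per row.
#' @param ref numeric matrix with the same number of columns.
#' @param chunk rows of `query` processed per block.
#' @return list with integer vector `index` and numeric vector `distance`.
#' @export
nearest_neighbours <- function(query, ref, chunk = 512L) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  if (nrow(query) == 0L) {
    return(list(index = integer(0), distance = numeric(0)))
  }
  if (nrow(ref) == 0L) {
    stop_synquant("reference point set is empty", "synquant_input_error")
  }
  nq <- nrow(query)
  ref_sq <- rowSums(ref^2)
  idx <- integer(nq)
  dst <- numeric(nq)
  for (start in seq(1L, nq, by = chunk)) {
    end <- min(start + chunk - 1L, nq)
    q <- query[start:end, , drop = FALSE]
    # squared distances via the expansion |q-r|^2 = |q|^2 - 2 q.r + |r|^2
    d2 <- outer(rowSums(q^2), ref_sq, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-d2, ties.method = "first")
    idx[start:end] <- j
    dst[start:end] <- sqrt(pmax(d2[cbind(seq_len(nrow(q)), j)], 0))
  }
  list(index = idx, distance = dst)
}
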