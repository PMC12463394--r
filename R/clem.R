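# CryoCLEM registration and puncta quantification.
#
# Fluorescence and EM views of the same grid square are registered from
# paired fiducials (centres of holes in the holey-carbon foil; at least 10
# are expected for a reliable fit). The default model is a similarity
# (scale + rotation + translation), solved in closed form (orthogonal
# Procrustes with scale); a full affine is available by flag. Psd95-GFP
# puncta are segmented by watershed on the smoothed image and quantified by
# their integrated intensity over the original pixels.

#' Fit a 2D point-set transform (similarity or affine)
#'
#' Least-squares fit of `dst ~ linear %*% src + translation`. The similarity
#' model constrains `linear = s * R` (closed-form Procrustes solution with
#' scale); the affine model solves the general 2x2 by linear least squares.
#'
#' @param src,dst n x 2 matrices of corresponding points (px).
#' @param model `"similarity"` or `"affine"`.
#' @param min_fiducials warn when fewer correspondences are supplied;
#'   default 10.
#' @return a `transform2d`: list with `linear` (2x2), `translation`,
#'   `model`, `rms_residual` (px), `n`.
#' @export
fit_point_transform <- function(src, dst,
                                model = c("similarity", "affine"),
                                min_fiducials = 10L) {
  model <- match.arg(model)
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst) || ncol(src) != 2L || ncol(dst) != 2L) {
    stop_synquant("src and dst must be equal-length n x 2 matrices",
                  "synquant_input_error")
  }
  n <- nrow(src)
  need <- if (model == "similarity") 2L else 3L
  if (n < need) {
    stop_synquant("too few points for this model",
                  "synquant_degenerate_error")
  }
  if (n < min_fiducials) {
    warning(sprintf("only %d fiducials (fewer than %d); fit may be unstable",
                    n, min_fiducials))
  }
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  X <- sweep(src, 2, mu_s); Y <- sweep(dst, 2, mu_d)
  if (model == "similarity") {
    var_x <- sum(X^2)
    if (var_x < 1e-12) {
      stop_synquant("degenerate (coincident) source points",
                    "synquant_degenerate_error")
    }
    S <- crossprod(Y, X) / n              # covariance dst~src
    sv <- svd(S)
    D <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
    R <- sv$u %*% D %*% t(sv$v)
    s <- sum(diag(D) * sv$d) * n / var_x
    A <- s * R
  } else {
    if (qr(X)$rank < 2L) {
      stop_synquant("collinear points cannot constrain an affine transform",
                    "synquant_degenerate_error")
    }
    A <- t(qr.solve(X, Y))                # Y = X %*% t(A)
  }
  tr <- mu_d - as.numeric(A %*% mu_s)
  fit <- src %*% t(A) + matrix(tr, n, 2, byrow = TRUE)
  rms <- sqrt(mean(rowSums((fit - dst)^2)))
  structure(list(linear = A, translation = tr, model = model,
                 rms_residual = rms, n = n),
            class = "transform2d")
}

#' Apply a 2D transform to points
#'
#' @param t a `transform2d`.
#' @param points n x 2 matrix (px).
#' @return n x 2 matrix of `linear %*% x + translation` per point.
#' @export
apply_transform <- function(t, points) {
  points <- as.matrix(points)
  points %*% t(t$linear) +
    matrix(t$translation, nrow(points), 2, byrow = TRUE)
}

#' Invert a 2D transform
#' @param t a `transform2d`.
#' @return a `transform2d` mapping dst back to src.
#' @export
invert_transform <- function(t) {
  Ai <- solve(t$linear)
  structure(list(linear = Ai, translation = as.numeric(-Ai %*% t$translation),
                 model = t$model, rms_residual = NA_real_, n = t$n),
            class = "transform2d")
}

#' Segment fluorescence puncta by watershed and integrate intensities
#'
#' Smooths the image with a Gaussian, thresholds at Otsu's level, splits
#' touching spots with the watershed transform seeded at local maxima of
#' the smoothed image, discards fragments below `min_area`, and integrates
#' each punctum over the ORIGINAL (unsmoothed) pixels.
#'
#' @param image 2D numeric matrix of intensities.
#' @param smoothing_sigma Gaussian sd in px; default 2.
#' @param min_area minimum punctum area in px; default 4.
#' @return a `puncta_set`: list with per-punctum data.frame `puncta`
#'   (label, centroid_x, centroid_y, area, integrated_intensity), the
#'   integer `label_image`, and `background_sum` such that
#'   `sum(integrated_intensity) + background_sum == sum(image)` exactly.
#' @export
segment_puncta <- function(image, smoothing_sigma = 2, min_area = 4L) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) {
    stop_synquant("image must be finite", "synquant_input_error")
  }
  empty <- function() {
    structure(list(
      puncta = data.frame(label = integer(0), centroid_x = numeric(0),
                          centroid_y = numeric(0), area = integer(0),
                          integrated_intensity = numeric(0)),
      label_image = matrix(0L, nrow(image), ncol(image)),
      background_sum = sum(image)), class = "puncta_set")
  }
  rng <- range(image)
  if (diff(rng) == 0) return(empty())
  sm <- EBImage::gblur(image, sigma = smoothing_sigma)
  smn <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  if (!any(smn > thr)) return(empty())
  # watershed basins over the whole smoothed image, so each punctum keeps
  # its tails; a basin is a punctum if its peak clears the Otsu threshold
  # and its above-threshold core reaches min_area
  lab <- EBImage::watershed(EBImage::Image(smn), tolerance = 0.02)
  lab <- as.matrix(EBImage::imageData(lab))
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  keep <- ids[vapply(ids, function(l) {
    core <- lab == l & smn > thr
    max(smn[lab == l]) > thr && sum(core) >= min_area
  }, logical(1))]
  out_lab <- matrix(0L, nrow(image), ncol(image))
  rows <- lapply(seq_along(keep), function(k) {
    px <- which(lab == keep[k], arr.ind = TRUE)
    out_lab[px] <<- k
    core <- which(lab == keep[k] & smn > thr, arr.ind = TRUE)
    data.frame(label = k,
               centroid_x = mean(core[, 1]),
               centroid_y = mean(core[, 2]),
               area = nrow(px),
               integrated_intensity = sum(image[px]))
  })
  puncta <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), centroid_x = numeric(0),
               centroid_y = numeric(0), area = integer(0),
               integrated_intensity = numeric(0))
  structure(list(puncta = puncta, label_image = out_lab,
                 background_sum = sum(image[out_lab == 0L])),
            class = "puncta_set")
}
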