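# Membrane-aligned molecular-crowding analysis.
#
# For each single tomographic slice a line profile (default 36 nm wide,
# 450 nm long) is taken perpendicular to the membrane; each profile is
# aligned to its own plasma-membrane intensity peak before averaging, so
# slight tilts of the membrane never smear membrane density into the
# cytoplasmic signal (the reason per-slice alignment is used instead of
# projecting slices). Slices whose peak sits far from the batch median are
# excluded as tilted. Crowding is then classified by a Welch two-tailed
# t-test comparing pooled voxel intensities in a membrane-proximal window
# (default 5-30 nm) against a distal window (default 50-200 nm), with
# Bonferroni correction across the synapse panel.

#' Specification of a membrane line profile
#'
#' @param anchor 3D point on/near the membrane (nm).
#' @param direction unit vector pointing into the cytoplasm.
#' @param width profile width in nm (averaged across lanes); default 36.
#' @param length profile length in nm; default 450.
#' @param start_offset nm before the anchor at which sampling starts
#'   (negative = behind the membrane); default -60 so the grid spans about
#'   [-60, +390] nm around the anchor.
#' @param slice_axis tomogram axis (1, 2 or 3) along which single slices are
#'   taken; must not be the profile direction's dominant axis.
#' @return a `profile_spec`.
#' @export
profile_spec <- function(anchor, direction, width = 36, length = 450,
                         start_offset = -60, slice_axis = 3L) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop_synquant("direction must be non-zero", "synquant_input_error")
  if (width <= 0 || length <= 0) {
    stop_synquant("width and length must be positive", "synquant_input_error")
  }
  structure(list(anchor = as.numeric(anchor), direction = direction / nrm,
                 width = width, length = length,
                 start_offset = start_offset,
                 slice_axis = as.integer(slice_axis)),
            class = "profile_spec")
}

# trilinear interpolation of vol$grid at nm positions (n x 3), outside -> NA
interp_trilinear <- function(vol, pts) {
  vs <- vol$voxel_size
  idx <- sweep(pts, 2, vol$origin) / vs   # 0-based fractional voxel coords
  d <- dim(vol$grid)
  i0 <- floor(idx)
  fr <- idx - i0
  ok <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= d[1] - 2 & i0[, 2] <= d[2] - 2 & i0[, 3] <= d[3] - 2
  # clamp exact upper boundary onto the last cell
  for (k in 1:3) {
    at_end <- abs(idx[, k] - (d[k] - 1)) < 1e-9
    ok <- ok | (at_end & i0[, k] == d[k] - 1)
    i0[at_end & i0[, k] == d[k] - 1, k] <- d[k] - 2
    fr[at_end, k] <- 1
  }
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i <- i0[ok, 1] + 1L; j <- i0[ok, 2] + 1L; k <- i0[ok, 3] + 1L
  fx <- fr[ok, 1]; fy <- fr[ok, 2]; fz <- fr[ok, 3]
  g <- vol$grid
  lin <- function(ii, jj, kk) g[cbind(ii, jj, kk)]
  c00 <- lin(i, j, k) * (1 - fx) + lin(i + 1L, j, k) * fx
  c10 <- lin(i, j + 1L, k) * (1 - fx) + lin(i + 1L, j + 1L, k) * fx
  c01 <- lin(i, j, k + 1L) * (1 - fx) + lin(i + 1L, j, k + 1L) * fx
  c11 <- lin(i, j + 1L, k + 1L) * (1 - fx) + lin(i + 1L, j + 1L, k + 1L) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Extract per-slice line profiles from a tomogram
#'
#' One profile per tomographic slice, never a projection across slices. At
#' each sample along the line the intensity is the mean over
#' `round(width / voxel_size)` parallel lanes perpendicular to the line
#' (within the slice plane), interpolated trilinearly. The membrane peak is
#' detected per slice as the intensity maximum within `peak_window` nm of
#' the anchor (after density-sign normalisation).
#'
#' @param vol a [tomogram] (density-positive).
#' @param spec a [profile_spec].
#' @param slice_range integer vector of 0-based slice indices along
#'   `spec$slice_axis`.
#' @param peak_window nm; half-width of the peak search window around the
#'   anchor.
#' @return list of `slice_profile` objects, each with `slice_index`,
#'   `offsets` (nm from the anchor), `intensities`, `peak_offset`.
#' @export
extract_profiles <- function(vol, spec, slice_range, peak_window = 15) {
  stopifnot(inherits(vol, "tomogram"), inherits(spec, "profile_spec"))
  vs <- vol$voxel_size
  sgn <- if (vol$density_sign == "positive") 1 else -1
  ax <- spec$slice_axis
  dirn <- spec$direction
  if (abs(dirn[ax]) > 1e-9) {
    stop_synquant("profile direction must lie within the slice plane",
                  "synquant_geometry_error")
  }
  # lane direction: perpendicular to the line, within the slice plane
  axv <- c(0, 0, 0); axv[ax] <- 1
  perp <- c(dirn[2] * axv[3] - dirn[3] * axv[2],
            dirn[3] * axv[1] - dirn[1] * axv[3],
            dirn[1] * axv[2] - dirn[2] * axv[1])
  perp <- perp / sqrt(sum(perp^2))
  n_lane <- max(1L, round(spec$width / vs))
  lane_off <- (seq_len(n_lane) - (n_lane + 1) / 2) * vs
  offsets <- seq(spec$start_offset, spec$start_offset + spec$length, by = vs)
  profiles <- vector("list", length(slice_range))
  for (si in seq_along(slice_range)) {
    s <- slice_range[si]
    base <- spec$anchor
    base[ax] <- vol$origin[ax] + s * vs
    pts <- matrix(base, nrow = length(offsets) * n_lane, ncol = 3,
                  byrow = TRUE)
    off_rep <- rep(offsets, each = n_lane)
    lane_rep <- rep(lane_off, times = length(offsets))
    pts <- pts + outer(off_rep, dirn) + outer(lane_rep, perp)
    vals <- interp_trilinear(vol, pts)
    if (anyNA(vals)) {
      stop_synquant(sprintf("profile exits the volume at slice %d", s),
                    "synquant_geometry_error")
    }
    inten <- sgn * colMeans(matrix(vals, nrow = n_lane))
    win <- which(abs(offsets) <= peak_window)
    pk <- win[which.max(inten[win])]
    profiles[[si]] <- structure(list(slice_index = s,
                                     offsets = offsets,
                                     intensities = inten,
                                     peak_offset = offsets[pk]),
                                class = "slice_profile")
  }
  profiles
}

#' Build a slice profile directly from sampled values
#'
#' Constructor used by the synthetic fast path and by tests: a profile on a
#' uniform nm grid with its membrane peak detected in a window around 0.
#'
#' @param offsets uniform nm grid (relative to the nominal membrane).
#' @param intensities one intensity per offset.
#' @param slice_index integer id.
#' @param peak_window nm half-width of the peak search window.
#' @return a `slice_profile`.
#' @export
slice_profile <- function(offsets, intensities, slice_index = 0L,
                          peak_window = 15) {
  win <- which(abs(offsets) <= peak_window)
  if (!length(win)) win <- seq_along(offsets)
  pk <- win[which.max(intensities[win])]
  structure(list(slice_index = as.integer(slice_index),
                 offsets = as.numeric(offsets),
                 intensities = as.numeric(intensities),
                 peak_offset = offsets[pk]),
            class = "slice_profile")
}

#' Align per-slice profiles to the membrane peak and average
#'
#' Each profile is shifted so its detected membrane peak sits at distance 0
#' (positive = into the cytoplasm). Profiles whose unaligned peak offset
#' deviates from the batch median by more than `tilt_tolerance` are marked
#' excluded with reason "tilted" and take no part in the mean/sd. The common
#' distance grid is the intersection of all included profiles' shifted
#' grids.
#'
#' @param profiles list of `slice_profile` objects (>= 3).
#' @param tilt_tolerance nm; default 6 (about 5 voxels at 1.194 nm/voxel).
#' @return an `aligned_profile_set`: list with `distance` grid, per-profile
#'   `matrix` of aligned intensities (rows = profiles), `mean_profile`,
#'   `sd_profile`, `included` data.frame, `n_used`, `n_excluded`.
#' @export
align_profiles <- function(profiles, tilt_tolerance = 6) {
  if (length(profiles) < 3L) {
    stop_synquant("need >= 3 profiles", "synquant_input_error")
  }
  pk <- vapply(profiles, function(p) p$peak_offset, 1)
  med <- stats::median(pk)
  excluded <- abs(pk - med) > tilt_tolerance
  reason <- ifelse(excluded, "tilted", "")
  if (all(excluded)) {
    stop_synquant("all profiles excluded as tilted", "synquant_empty_set")
  }
  keep <- which(!excluded)
  step <- diff(profiles[[keep[1]]]$offsets[1:2])
  # shifted grids are all offset by integer multiples of the sample spacing,
  # so the common grid is exact (no re-interpolation)
  lo <- max(vapply(keep, function(i)
    min(profiles[[i]]$offsets - profiles[[i]]$peak_offset), 1))
  hi <- min(vapply(keep, function(i)
    max(profiles[[i]]$offsets - profiles[[i]]$peak_offset), 1))
  grid <- seq(ceiling(lo / step - 1e-9) * step,
              floor(hi / step + 1e-9) * step, by = step)
  mat <- t(vapply(keep, function(i) {
    p <- profiles[[i]]
    shifted <- p$offsets - p$peak_offset
    j <- round((grid - shifted[1]) / step) + 1L
    p$intensities[j]
  }, numeric(length(grid))))
  structure(list(
    distance = grid,
    matrix = mat,
    mean_profile = colMeans(mat),
    sd_profile = apply(mat, 2, stats::sd),
    included = data.frame(
      slice_index = vapply(profiles, function(p) p$slice_index, 1L),
      peak_offset = pk, included = !excluded, reason = reason),
    n_used = length(keep),
    n_excluded = sum(excluded)
  ), class = "aligned_profile_set")
}

# Welch two-sample t statistic and two-sided p (own closed form is in tests)
welch_test <- function(a, b) {
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Classify proximal-versus-distal molecular crowding
#'
#' Pools all aligned per-slice voxel intensities falling in the proximal
#' window (default 5-30 nm from the membrane peak) and in the distal window
#' (default 50-200 nm), compares them with a Welch two-tailed t-test, and
#' classifies the synapse at the Bonferroni-corrected level
#' `alpha / bonferroni_m`: `"higher"` (proximal mean larger and significant),
#' `"lower"`, or `"not_different"`.
#'
#' @param aligned an `aligned_profile_set`.
#' @param proximal,distal nm intervals `c(lo, hi)`.
#' @param alpha family-wise significance level; default 0.05.
#' @param bonferroni_m number of synapses in the tested panel; default 1.
#' @return a `crowding_result`: list with `t_statistic`, `p_value`,
#'   `n_prox`, `n_dist`, `mean_prox`, `mean_dist`, `crowding_class`,
#'   `alpha`, `bonferroni_m`.
#' @export
classify_crowding <- function(aligned, proximal = c(5, 30),
                              distal = c(50, 200), alpha = 0.05,
                              bonferroni_m = 1L) {
  stopifnot(inherits(aligned, "aligned_profile_set"))
  if (bonferroni_m < 1L) {
    stop_synquant("bonferroni_m must be >= 1", "synquant_input_error")
  }
  g <- aligned$distance
  ip <- g >= proximal[1] & g <= proximal[2]
  id <- g >= distal[1] & g <= distal[2]
  prox <- as.numeric(aligned$matrix[, ip])
  dist <- as.numeric(aligned$matrix[, id])
  if (length(prox) < 2L || length(dist) < 2L) {
    stop_synquant("fewer than 2 samples in a crowding window",
                  "synquant_insufficient_data")
  }
  if (stats::sd(prox) == 0 && stats::sd(dist) == 0) {
    wt <- list(t = 0, p = 1)
  } else {
    wt <- welch_test(prox, dist)
  }
  thr <- alpha / bonferroni_m
  cls <- if (wt$p < thr && mean(prox) > mean(dist)) "higher"
         else if (wt$p < thr && mean(prox) < mean(dist)) "lower"
         else "not_different"
  structure(list(t_statistic = wt$t, p_value = wt$p,
                 n_prox = length(prox), n_dist = length(dist),
                 mean_prox = mean(prox), mean_dist = mean(dist),
                 proximal_window = proximal, distal_window = distal,
                 alpha = alpha, bonferroni_m = as.integer(bonferroni_m),
                 crowding_class = cls),
            class = "crowding_result")
}

#' @export
print.crowding_result <- function(x, ...) {
  cat(sprintf(
    "<crowding_result> %s (t=%.3f, p=%.3g, n=%d/%d, alpha/m=%.4g)\n",
    x$crowding_class, x$t_statistic, x$p_value, x$n_prox, x$n_dist,
    x$alpha / x$bonferroni_m))
  invisible(x)
}
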