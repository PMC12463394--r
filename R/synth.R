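# Synthetic synapse scenes with known ground truth.
#
# The generator emulates the geometry the analyses assume: paired PreSM/PoSM
# membrane surfaces at a controllable separation (the measured cleft heights
# fall in the ~27-37 nm range, 33 nm on average), receptor point patterns on
# the PoSM drawn from a Thomas-type clustered process, optional lateral
# two-plateau separation maps (bimodal clefts), and rendered noisy volumes
# with a double-Gaussian bilayer ridge, adjustable cytoplasmic crowding and
# ~14 nm receptor ectodomain blobs. Every generator is a pure function of
# its seed.

surface_height <- function(geometry, y, z, undulation_amp, undulation_wavelength) {
  switch(geometry,
    plane = rep(0, length(y)),
    undulating = undulation_amp * sin(2 * pi * y / undulation_wavelength) *
      sin(2 * pi * z / undulation_wavelength),
    stop_synquant("unknown sheet geometry", "synquant_input_error"))
}

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

separation_at <- function(separation, y) {
  if (length(separation) == 1L) rep(separation, length(y))
  else ifelse(y < 0, separation[1], separation[2])
}

#' Generate a synthetic synapse scene
#'
#' Builds paired PreSM/PoSM membrane point samples, a clustered receptor
#' point pattern on the PoSM (Thomas process: Gaussian dispersion of
#' `cluster_sigma` nm around uniformly placed centres with a minimum
#' pairwise guard distance), and ground-truth tables (cluster labels and
#' centres, per-PoSM-point in-cleft flags). Sheet geometries put the PoSM at
#' x = 0 (cytoplasm at x < 0) and the PreSM at x = separation; sphere
#' geometry uses concentric shells. With a length-2 `separation`, the cleft
#' is a lateral two-plateau step (first value for y < 0).
#'
#' @param geometry `"plane"`, `"undulating"` or `"sphere"`.
#' @param separation nm; scalar, or length 2 for a two-plateau cleft.
#' @param extent lateral scene size in nm (sheets: side of the square PoSM
#'   patch; sphere: PoSM radius is `extent / 2 / pi` so patch areas are
#'   comparable). Default 1300 nm, the field of view the analyses target.
#' @param spacing membrane sample pitch in nm (regular grid / Fibonacci
#'   lattice); default 15, giving segmentation-scale point counts.
#' @param presm_extent lateral extent of the PreSM patch (sheets only);
#'   defaults to `extent`. A smaller PreSM leaves perisynaptic PoSM.
#' @param n_clusters number of receptor clusters.
#' @param receptors_per_cluster receptors per cluster; default 10, the
#'   average cluster size the analyses report.
#' @param cluster_sigma Thomas dispersion in nm; default 20.
#' @param guard_distance minimum pairwise centre separation in nm
#'   (surface distance); default 250.
#' @param centre_margin keep cluster centres this many nm inside the patch
#'   border; default `2 * cluster_sigma`.
#' @param surface_noise sd (nm) of Gaussian displacement along the surface
#'   normal applied to membrane samples; default 0.
#' @param cleft_cutoff nm used for the ground-truth in-cleft flags;
#'   default 60.
#' @param undulation_amp,undulation_wavelength nm; sheet undulation.
#' @param seed integer seed; the scene is a pure function of it.
#' @return a `synapse_scene`: list with `presm`, `posm`, `receptors`
#'   ([point_table]s), `receptor_truth` (data.frame index/cluster),
#'   `cluster_centres`, `cleft_zone_truth` (logical per PoSM point),
#'   `separation`, `geometry`, `seed`.
#' @export
make_synapse_scene <- function(geometry = c("plane", "undulating", "sphere"),
                               separation = 33,
                               extent = 1300,
                               spacing = 15,
                               presm_extent = extent,
                               n_clusters = 2L,
                               receptors_per_cluster = 10L,
                               cluster_sigma = 20,
                               guard_distance = 250,
                               centre_margin = 2 * cluster_sigma,
                               surface_noise = 0,
                               cleft_cutoff = 60,
                               undulation_amp = 20,
                               undulation_wavelength = 400,
                               seed = 1L) {
  geometry <- match.arg(geometry)
  if (any(separation <= 0)) {
    stop_synquant("separation must be positive", "synquant_input_error")
  }
  with_seed(seed, {
    if (geometry == "sphere") {
      r_po <- extent / 2 / pi
      n_po <- max(16L, round(4 * pi * r_po^2 / spacing^2))
      r_pre <- r_po + separation[1]
      n_pre <- max(16L, round(4 * pi * r_pre^2 / spacing^2))
      posm_xyz <- fibonacci_sphere(n_po, r_po)
      presm_xyz <- fibonacci_sphere(n_pre, r_pre)
      posm_normal <- posm_xyz / sqrt(rowSums(posm_xyz^2))
      presm_normal <- presm_xyz / sqrt(rowSums(presm_xyz^2))
    } else {
      g_po <- seq(-extent / 2, extent / 2, by = spacing)
      yy <- rep(g_po, times = length(g_po))
      zz <- rep(g_po, each = length(g_po))
      x0 <- surface_height(geometry, yy, zz, undulation_amp,
                           undulation_wavelength)
      posm_xyz <- cbind(x = x0, y = yy, z = zz)
      g_pre <- seq(-presm_extent / 2, presm_extent / 2, by = spacing)
      y2 <- rep(g_pre, times = length(g_pre))
      z2 <- rep(g_pre, each = length(g_pre))
      x1 <- surface_height(geometry, y2, z2, undulation_amp,
                           undulation_wavelength) +
        separation_at(separation, y2)
      presm_xyz <- cbind(x = x1, y = y2, z = z2)
      posm_normal <- matrix(rep(c(1, 0, 0), each = nrow(posm_xyz)), ncol = 3)
      presm_normal <- matrix(rep(c(1, 0, 0), each = nrow(presm_xyz)), ncol = 3)
    }

    # receptor Thomas process on the PoSM
    centres <- NULL
    rec_xyz <- matrix(numeric(0), ncol = 3)
    rec_cluster <- integer(0)
    if (n_clusters > 0L) {
      place <- function() {
        if (geometry == "sphere") {
          r_po <- extent / 2 / pi
          fibonacci_sphere(20000L, 1)[sample.int(20000L, 1L), ] * r_po
        } else {
          lim <- extent / 2 - centre_margin
          y <- stats::runif(1, -lim, lim)
          z <- stats::runif(1, -lim, lim)
          c(surface_height(geometry, y, z, undulation_amp,
                           undulation_wavelength), y, z)
        }
      }
      centres <- matrix(NA_real_, nrow = n_clusters, ncol = 3)
      for (ci in seq_len(n_clusters)) {
        ok <- FALSE
        for (try in seq_len(2000L)) {
          cand <- place()
          if (ci == 1L ||
              all(sqrt(rowSums(sweep(centres[seq_len(ci - 1L), , drop = FALSE],
                                     2, cand)^2)) >= guard_distance)) {
            centres[ci, ] <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop_synquant(
            "cannot place cluster centres at the requested guard distance",
            "synquant_generation_error")
        }
      }
      for (ci in seq_len(n_clusters)) {
        if (geometry == "sphere") {
          r_po <- extent / 2 / pi
          # Gaussian dispersion in the tangent plane, re-projected to the shell
          nrm <- centres[ci, ] / sqrt(sum(centres[ci, ]^2))
          a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          e1 <- a - sum(a * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
          e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
                  nrm[3] * e1[1] - nrm[1] * e1[3],
                  nrm[1] * e1[2] - nrm[2] * e1[1])
          off <- matrix(stats::rnorm(2L * receptors_per_cluster,
                                     sd = cluster_sigma), ncol = 2)
          p <- sweep(off[, 1, drop = FALSE] %*% rbind(e1) +
                       off[, 2, drop = FALSE] %*% rbind(e2), 2,
                     centres[ci, ], "+")
          p <- p / sqrt(rowSums(p^2)) * r_po
        } else {
          y <- centres[ci, 2] + stats::rnorm(receptors_per_cluster,
                                             sd = cluster_sigma)
          z <- centres[ci, 3] + stats::rnorm(receptors_per_cluster,
                                             sd = cluster_sigma)
          p <- cbind(surface_height(geometry, y, z, undulation_amp,
                                    undulation_wavelength), y, z)
        }
        rec_xyz <- rbind(rec_xyz, p)
        rec_cluster <- c(rec_cluster, rep(ci, receptors_per_cluster))
      }
    }

    # ground truth in-cleft flags BEFORE noise (exact geometry)
    nn <- nearest_neighbours(posm_xyz, presm_xyz)
    cleft_truth <- nn$distance <= cleft_cutoff

    if (surface_noise > 0) {
      posm_xyz <- posm_xyz +
        posm_normal * stats::rnorm(nrow(posm_xyz), sd = surface_noise)
      presm_xyz <- presm_xyz +
        presm_normal * stats::rnorm(nrow(presm_xyz), sd = surface_noise)
    }

    structure(list(
      presm = point_table(presm_xyz, "PreSM"),
      posm = point_table(posm_xyz, "PoSM"),
      receptors = point_table(rec_xyz, "receptor"),
      receptor_truth = data.frame(index = seq_along(rec_cluster),
                                  cluster = rec_cluster),
      cluster_centres = centres,
      cleft_zone_truth = cleft_truth,
      separation = separation,
      geometry = geometry,
      extent = extent,
      spacing = spacing,
      undulation_amp = undulation_amp,
      undulation_wavelength = undulation_wavelength,
      surface_noise = surface_noise,
      seed = seed
    ), class = "synapse_scene")
  })
}

#' Rendering parameters for synthetic tomograms
#'
#' @param voxel_size nm per voxel; default 1.194, the binning level of the
#'   analysed maps (11.94 Angstrom).
#' @param bilayer_gap nm between the two leaflet ridges; default 5.
#' @param bilayer_width Gaussian sd of each leaflet ridge in nm; default 2.
#' @param membrane_amp ridge amplitude (a.u.).
#' @param receptor_height nm the receptor ectodomain extends into the cleft;
#'   default 14.
#' @param receptor_amp,receptor_radius blob amplitude (a.u.) and lateral
#'   Gaussian radius (nm) of rendered receptors.
#' @param crowding_profile function of signed distance from the PoSM
#'   (positive into the PoSM cytoplasm, nm) giving the mean cytoplasmic
#'   density; default a flat 1.0 inside the cytoplasm and 0.3 in the cleft.
#' @param noise_sigma sd of additive Gaussian noise (a.u.).
#' @param blur_anisotropy optional z-elongation factor (>1 blurs z more),
#'   emulating missing-wedge anisotropy coarsely; `NULL` disables.
#' @param blur_sigma base blur sd in nm when `blur_anisotropy` is set.
#' @return a `render_params` list.
#' @export
render_params <- function(voxel_size = 1.194, bilayer_gap = 5,
                          bilayer_width = 2, membrane_amp = 2,
                          receptor_height = 14, receptor_amp = 1,
                          receptor_radius = 4,
                          crowding_profile = NULL,
                          noise_sigma = 0.1,
                          blur_anisotropy = NULL, blur_sigma = 1.5) {
  if (voxel_size <= 0 || receptor_height < 0 || noise_sigma < 0) {
    stop_synquant("invalid render parameters", "synquant_input_error")
  }
  if (is.null(crowding_profile)) {
    crowding_profile <- function(s) ifelse(s > 0, 1.0, 0.3)
  }
  structure(list(voxel_size = voxel_size, bilayer_gap = bilayer_gap,
                 bilayer_width = bilayer_width, membrane_amp = membrane_amp,
                 receptor_height = receptor_height,
                 receptor_amp = receptor_amp,
                 receptor_radius = receptor_radius,
                 crowding_profile = crowding_profile,
                 noise_sigma = noise_sigma,
                 blur_anisotropy = blur_anisotropy,
                 blur_sigma = blur_sigma),
            class = "render_params")
}

gauss_blur_1d <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * pad[(i - 1L) + seq_len(n), , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

#' Render a synthetic scene as a noisy tomogram
#'
#' Draws the two membranes as double-Gaussian bilayer ridges around their
#' true surfaces, fills each cytoplasm according to the crowding profile,
#' adds a Gaussian blob of height `receptor_height` on the cleft side of
#' the PoSM for every receptor, then adds iid Gaussian noise (and an
#' optional anisotropic blur). Sheet geometries only; the volume covers the
#' axis-aligned box given by `extent` (nm, voxel-centre coordinates).
#'
#' @param scene a `synapse_scene` with sheet geometry.
#' @param params a [render_params].
#' @param extent list with nm ranges `x`, `y`, `z` (each `c(lo, hi)`).
#' @param seed integer seed for the noise.
#' @param slice_shift optional function of z (nm) giving an extra x-shift of
#'   both membranes per slice, emulating tilted slices.
#' @return a [tomogram] (density-positive).
#' @export
render_tomogram <- function(scene, params = render_params(),
                            extent = list(x = c(-420, 80),
                                          y = c(-40, 40),
                                          z = c(-20, 20)),
                            seed = 1L,
                            slice_shift = NULL) {
  stopifnot(inherits(scene, "synapse_scene"), inherits(params, "render_params"))
  if (scene$geometry == "sphere") {
    stop_synquant("volume rendering supports sheet geometries only",
                  "synquant_geometry_error")
  }
  vs <- params$voxel_size
  gx <- seq(extent$x[1], extent$x[2], by = vs)
  gy <- seq(extent$y[1], extent$y[2], by = vs)
  gz <- seq(extent$z[1], extent$z[2], by = vs)
  if (length(gx) < 2L || length(gy) < 2L || length(gz) < 2L) {
    stop_synquant("grid too small for the scene", "synquant_geometry_error")
  }
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  yy <- rep(gy, times = nz)
  zz <- rep(gz, each = ny)
  x_po <- surface_height(scene$geometry, yy, zz, scene$undulation_amp,
                         scene$undulation_wavelength)
  x_pre <- x_po + separation_at(scene$separation, yy)
  if (!is.null(slice_shift)) {
    sh <- slice_shift(zz)
    x_po <- x_po + sh
    x_pre <- x_pre + sh
  }
  ridge <- function(s) {
    params$membrane_amp *
      (exp(-(s - params$bilayer_gap / 2)^2 / (2 * params$bilayer_width^2)) +
         exp(-(s + params$bilayer_gap / 2)^2 / (2 * params$bilayer_width^2)))
  }
  vol <- array(0, dim = c(nx, ny, nz))
  crowd <- params$crowding_profile
  for (col in seq_len(ny * nz)) {
    s_po <- x_po[col] - gx          # + into PoSM cytoplasm (x < membrane)
    s_pre <- gx - x_pre[col]        # + into PreSM cytoplasm
    dens <- ridge(s_po) + ridge(s_pre) +
      crowd(s_po) * (s_po > params$bilayer_gap / 2) +
      crowd(s_pre) * (s_pre > params$bilayer_gap / 2)
    j <- (col - 1L) %% ny + 1L
    k <- (col - 1L) %/% ny + 1L
    vol[, j, k] <- dens
  }
  # receptor ectodomain blobs on the cleft side of the PoSM
  if (nrow(scene$receptors) > 0L) {
    rw <- params$receptor_radius
    h <- params$receptor_height
    for (ri in seq_len(nrow(scene$receptors))) {
      r <- as.numeric(scene$receptors[ri, c("x", "y", "z")])
      iy <- which(abs(gy - r[2]) <= 3 * rw)
      iz <- which(abs(gz - r[3]) <= 3 * rw)
      ix <- which(gx >= r[1] & gx <= r[1] + h)
      if (!length(iy) || !length(iz) || !length(ix)) next
      wy <- exp(-(gy[iy] - r[2])^2 / (2 * rw^2))
      wz <- exp(-(gz[iz] - r[3])^2 / (2 * rw^2))
      blob <- params$receptor_amp *
        outer(rep(1, length(ix)), as.numeric(outer(wy, wz)))
      vol[ix, iy, iz] <- vol[ix, iy, iz] +
        array(blob, dim = c(length(ix), length(iy), length(iz)))
    }
  }
  vol <- with_seed(seed, {
    if (params$noise_sigma > 0) {
      vol <- vol + array(stats::rnorm(length(vol), sd = params$noise_sigma),
                         dim = dim(vol))
    }
    vol
  })
  if (!is.null(params$blur_anisotropy)) {
    s_vox <- params$blur_sigma / vs
    vol <- gauss_blur_1d(vol, s_vox, 1L)
    vol <- gauss_blur_1d(vol, s_vox, 2L)
    vol <- gauss_blur_1d(vol, s_vox * params$blur_anisotropy, 3L)
  }
  tomogram(vol, voxel_size = vs,
           origin = c(extent$x[1], extent$y[1], extent$z[1]))
}

#' Simulate an aligned-profile batch directly (fast path)
#'
#' Draws per-slice line profiles with a bilayer membrane ridge at 0, a flat
#' cytoplasmic plateau with an optional proximal crowding bump, iid Gaussian
#' noise, and integer-voxel peak jitter emulating slice-to-slice tilt. Used
#' for statistical calibration of the crowding test without rendering
#' volumes.
#'
#' @param n_slices profiles per synapse; default 31.
#' @param voxel_size nm; default 1.194.
#' @param span nm range of offsets around the membrane; default
#'   `c(-60, 390)`.
#' @param cyto_level cytoplasmic plateau (a.u.).
#' @param cleft_level density on the far (cleft) side of the membrane.
#' @param bump_amp additive proximal bump amplitude (a.u.); 0 = flat.
#' @param bump_window nm window of the bump; default `c(5, 30)`.
#' @param membrane_amp,bilayer_gap,bilayer_width ridge shape (a.u., nm, nm).
#' @param noise_sigma iid noise sd (a.u.); default 0.1.
#' @param jitter_vox max integer-voxel peak jitter (uniform); default 2.
#' @param seed integer seed.
#' @return list of `slice_profile` objects.
#' @export
simulate_profile_set <- function(n_slices = 31L, voxel_size = 1.194,
                                 span = c(-60, 390),
                                 cyto_level = 1, cleft_level = 0.3,
                                 bump_amp = 0, bump_window = c(5, 30),
                                 membrane_amp = 2, bilayer_gap = 5,
                                 bilayer_width = 2,
                                 noise_sigma = 0.1, jitter_vox = 2L,
                                 seed = 1L) {
  with_seed(seed, {
    offs <- seq(span[1], span[2], by = voxel_size)
    lapply(seq_len(n_slices), function(s) {
      shift <- if (jitter_vox > 0)
        sample(-jitter_vox:jitter_vox, 1L) * voxel_size else 0
      t <- offs - shift                     # membrane truly at `shift`
      ridge <- membrane_amp *
        (exp(-(t - bilayer_gap / 2)^2 / (2 * bilayer_width^2)) +
           exp(-(t + bilayer_gap / 2)^2 / (2 * bilayer_width^2)))
      cyto <- ifelse(t > bilayer_gap / 2, cyto_level,
                     ifelse(t < -bilayer_gap / 2, cleft_level, 0))
      bump <- bump_amp * (t >= bump_window[1] & t <= bump_window[2])
      v <- ridge + cyto + bump + stats::rnorm(length(t), sd = noise_sigma)
      slice_profile(offs, v, slice_index = s)
    })
  })
}

#' Generate paired 2D fiducial point lists under a known transform
#'
#' The destination list is the similarity/affine transform applied to the
#' source list plus isotropic Gaussian noise, emulating hole-centre
#' fiducials used to register cryoFM to cryoEM images.
#'
#' @param scale,rotation_deg,translation similarity parameters (px).
#' @param linear optional explicit 2x2 matrix overriding scale/rotation
#'   (for affine fixtures).
#' @param n_points number of fiducials; default 10, the minimum hole count
#'   used for registration.
#' @param noise_sigma px sd of iid Gaussian noise on the destination.
#' @param extent px; sources drawn uniformly in `[0, extent]^2`.
#' @param seed integer seed.
#' @return list with matrices `src`, `dst` and the true `transform`
#'   (`linear`, `translation`).
#' @export
make_fiducial_scene <- function(scale = 1, rotation_deg = 0,
                                translation = c(0, 0), linear = NULL,
                                n_points = 10L, noise_sigma = 0,
                                extent = 2048, seed = 1L) {
  if (n_points < 3L) {
    stop_synquant("need n_points >= 3", "synquant_input_error")
  }
  th <- rotation_deg * pi / 180
  A <- linear %||% (scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2))
  with_seed(seed, {
    src <- matrix(stats::runif(2L * n_points, 0, extent), ncol = 2)
    dst <- src %*% t(A) + matrix(translation, n_points, 2, byrow = TRUE)
    if (noise_sigma > 0) {
      dst <- dst + matrix(stats::rnorm(2L * n_points, sd = noise_sigma),
                          ncol = 2)
    }
    list(src = src, dst = dst,
         transform = list(linear = A, translation = as.numeric(translation)))
  })
}
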