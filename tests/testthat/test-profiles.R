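# Membrane-aligned crowding profiles: extraction, alignment, classification.

test_that("profile defaults match the analysis geometry", {
  sp <- profile_spec(anchor = c(0, 0, 0), direction = c(-1, 0, 0))
  expect_equal(sp$width, 36)
  expect_equal(sp$length, 450)
  expect_error(profile_spec(c(0, 0, 0), c(0, 0, 0)),
               class = "synquant_input_error")
})

test_that("profiles of a constant volume are constant", {
  vol <- tomogram(array(7, dim = c(120, 40, 10)), voxel_size = 4,
                  origin = c(-240, -80, 0))
  sp <- profile_spec(anchor = c(0, 0, 0), direction = c(-1, 0, 0),
                     width = 36, length = 160, start_offset = -40)
  prs <- extract_profiles(vol, sp, slice_range = 3:7)
  expect_length(prs, 5L)
  for (p in prs) expect_equal(p$intensities, rep(7, length(p$offsets)))
})

test_that("a profile that exits the volume names the offending slice", {
  vol <- tomogram(array(0, dim = c(20, 20, 6)), voxel_size = 4)
  sp <- profile_spec(anchor = c(40, 40, 0), direction = c(-1, 0, 0),
                     width = 16, length = 400, start_offset = 0)
  err <- expect_error(extract_profiles(vol, sp, slice_range = 2:4),
                      class = "synquant_geometry_error")
  expect_match(conditionMessage(err), "slice 2")
})

test_that("per-slice peaks land on the rendered membrane position", {
  sc <- make_synapse_scene("plane", separation = 33, extent = 200,
                           spacing = 10, n_clusters = 0, seed = 1)
  vol <- render_tomogram(sc, render_params(noise_sigma = 0),
                         extent = list(x = c(-260, 60), y = c(-40, 40),
                                       z = c(-12, 12)), seed = 1)
  sp <- profile_spec(anchor = c(0, 0, 0), direction = c(-1, 0, 0),
                     length = 200, start_offset = -30)
  prs <- extract_profiles(vol, sp, slice_range = 5:15)
  # the cytoplasmic leaflet crest sits half a bilayer gap from x = 0;
  # detected peaks must agree within one voxel
  for (p in prs) {
    expect_lt(abs(abs(p$peak_offset) - 2.5), vol$voxel_size + 1e-9)
  }
})

test_that("alignment undoes integer-voxel shifts exactly", {
  base <- simulate_profile_set(n_slices = 3, noise_sigma = 0,
                               jitter_vox = 0, seed = 1)
  # already aligned: the set mean equals any single profile
  al <- align_profiles(base)
  expect_equal(al$n_used, 3L)
  j <- match(round(al$distance + base[[1]]$peak_offset, 6),
             round(base[[1]]$offsets, 6))
  expect_equal(al$mean_profile, base[[1]]$intensities[j])

  # a circularly shifted copy aligns back onto its unshifted twin
  p <- base[[1]]
  k <- 3L
  shifted <- slice_profile(p$offsets,
                           c(tail(p$intensities, -k), rep(p$intensities[length(p$intensities)], k)),
                           slice_index = 9L)
  # shifting the data left by k voxels moves the peak by -k voxels
  expect_equal(shifted$peak_offset, p$peak_offset - k * diff(p$offsets[1:2]))
  al2 <- align_profiles(list(p, p, shifted))
  m <- al2$matrix
  expect_equal(m[3, ], m[1, ])
})

test_that("profiles with outlying peaks are excluded as tilted", {
  base <- simulate_profile_set(n_slices = 6, noise_sigma = 0,
                               jitter_vox = 0, seed = 2)
  p <- base[[1]]
  vs <- diff(p$offsets[1:2])
  k <- round(15 / vs)
  tilted <- slice_profile(p$offsets + k * vs, p$intensities,
                          slice_index = 99L, peak_window = 30)
  al <- align_profiles(c(base, list(tilted)), tilt_tolerance = 6)
  expect_equal(al$n_excluded, 1L)
  row <- al$included[al$included$slice_index == 99L, ]
  expect_false(row$included)
  expect_equal(row$reason, "tilted")
  expect_error(align_profiles(base[1:2]), class = "synquant_input_error")
})

test_that("crowding classification reproduces an independent Welch test", {
  # flat intensities: t = 0, not different
  flat <- lapply(1:5, function(i) {
    slice_profile(seq(-20, 220, by = 2), rep(3, 121), slice_index = i)
  })
  al <- align_profiles(flat)
  cr <- classify_crowding(al, bonferroni_m = 10)
  expect_equal(cr$t_statistic, 0)
  expect_equal(cr$crowding_class, "not_different")

  # N(1.2, 0.1) proximal vs N(1.0, 0.1) distal at panel scale
  set.seed(31)
  grid <- seq(-20, 220, by = 0.35)
  mk <- function(i) {
    v <- ifelse(grid >= 5 & grid <= 30, rnorm(length(grid), 1.2, 0.1),
                rnorm(length(grid), 1.0, 0.1))
    v[abs(grid) < 1] <- 5  # sharp membrane peak at 0
    slice_profile(grid, v, slice_index = i)
  }
  al2 <- align_profiles(lapply(1:9, mk))
  cr2 <- classify_crowding(al2, bonferroni_m = 30)
  expect_equal(cr2$crowding_class, "higher")
  g <- al2$distance
  prox <- as.numeric(al2$matrix[, g >= 5 & g <= 30])
  dist <- as.numeric(al2$matrix[, g >= 50 & g <= 200])
  orc <- welch_oracle(prox, dist)
  expect_equal(cr2$t_statistic, orc$t, tolerance = 1e-6)
  expect_equal(cr2$p_value, orc$p, tolerance = 1e-6)
  expect_equal(cr2$n_prox, length(prox))
})

test_that("affine intensity maps leave the classification invariant", {
  prs <- simulate_profile_set(bump_amp = 0.2, seed = 7)
  al <- align_profiles(prs)
  cr <- classify_crowding(al, bonferroni_m = 30)
  scaled <- lapply(prs, function(p) {
    slice_profile(p$offsets, 3.7 * p$intensities + 11, p$slice_index)
  })
  cr2 <- classify_crowding(align_profiles(scaled), bonferroni_m = 30)
  expect_equal(cr2$t_statistic, cr$t_statistic, tolerance = 1e-9)
  expect_identical(cr2$crowding_class, cr$crowding_class)
})

test_that("translating the volume along the profile axis changes nothing", {
  sc <- make_synapse_scene("plane", separation = 33, extent = 200,
                           spacing = 10, n_clusters = 0, seed = 1)
  ext1 <- list(x = c(-260, 60), y = c(-40, 40), z = c(-12, 12))
  v1 <- render_tomogram(sc, render_params(noise_sigma = 0), ext1, seed = 1)
  # same physical scene, grid shifted by 5 voxels along x
  sh <- 5 * 1.194
  ext2 <- list(x = c(-260 - sh, 60 - sh), y = c(-40, 40), z = c(-12, 12))
  v2 <- render_tomogram(sc, render_params(noise_sigma = 0), ext2, seed = 1)
  sp <- profile_spec(anchor = c(0, 0, 0), direction = c(-1, 0, 0),
                     length = 200, start_offset = -30)
  a1 <- align_profiles(extract_profiles(v1, sp, 5:12))
  a2 <- align_profiles(extract_profiles(v2, sp, 5:12))
  expect_equal(a1$mean_profile, a2$mean_profile, tolerance = 1e-9)
})
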