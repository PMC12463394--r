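# Volume, point-table and mesh I/O: unit conventions and lossless round trips.

test_that("MRC round trip is bit-exact for float32 and converts A to nm", {
  set.seed(11)
  vals <- rnorm(32^3)
  # snap to float32-representable values so round-tripping is bit-exact
  vals <- readBin(writeBin(vals, raw(), size = 4), "numeric", 32^3, size = 4)
  vol <- tomogram(array(vals, dim = c(32, 32, 32)), voxel_size = 1.194)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(as.numeric(back$grid), vals)
  expect_equal(back$voxel_size, 1.194, tolerance = 1e-6)
  expect_equal(dim(back$grid), c(32L, 32L, 32L))
})

test_that("a ramp volume reads back with the stats of the source array", {
  ramp <- array(seq(0, 1, length.out = 32^3), dim = c(32, 32, 32))
  ramp[] <- readBin(writeBin(as.numeric(ramp), raw(), size = 4),
                    "numeric", 32^3, size = 4)
  vol <- tomogram(ramp, voxel_size = 0.8)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_volume(vol, path)
  g <- read_volume(path)$grid
  expect_equal(min(g), min(ramp))
  expect_equal(max(g), max(ramp))
  expect_equal(mean(g), mean(ramp), tolerance = 1e-7)
})

test_that("written header pixel size equals 10 x voxel_size (independent parse)", {
  set.seed(7)
  for (vs in runif(20, 0.3, 3)) {
    vol <- tomogram(array(0, dim = c(4, 5, 6)), voxel_size = vs)
    path <- withr::local_tempfile(fileext = ".mrc")
    write_volume(vol, path)
    con <- file(path, "rb")
    hdr_i <- readBin(con, "integer", n = 10, size = 4, endian = "little")
    cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
    close(con)
    px_angstrom <- cella / hdr_i[8:10]
    expect_lt(max(abs(px_angstrom - 10 * vs)), 1e-4)
  }
})

test_that("malformed and inverted volumes are handled", {
  path <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(1, 2000)), path)
  expect_error(read_volume(path), class = "synquant_format_error")
  expect_error(read_volume("does-not-exist.mrc"), class = "synquant_io_error")

  vol <- tomogram(array(as.numeric(1:8), dim = c(2, 2, 2)), voxel_size = 1)
  p2 <- withr::local_tempfile(fileext = ".mrc")
  write_volume(vol, p2)
  expect_equal(as.numeric(read_volume(p2, invert = TRUE)$grid),
               -as.numeric(1:8))
})

test_that("point tables convert voxel units exactly once", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "100,0,0", "0,50,25"), path)
  pt <- read_points(path, units = "voxel", voxel_size = 1.194)
  expect_equal(pt$x[1], 119.4)
  expect_equal(unlist(pt[2, c("x", "y", "z")], use.names = FALSE),
               c(0, 59.7, 29.85))
  # nm units ignore voxel_size entirely
  pt_nm <- read_points(path, units = "nm", voxel_size = 999)
  expect_equal(pt_nm$x[1], 100)
})

test_that("point tables round trip and handle edge cases", {
  pt <- point_table(matrix(c(1.25, -2.5, 3, 0.1, 0.2, 0.3), ncol = 3,
                           byrow = TRUE), label = c("PreSM", "PoSM"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_points(pt, path)
  back <- read_points(path)
  expect_equal(back$x, pt$x)
  expect_equal(back$y, pt$y)
  expect_equal(back$z, pt$z)
  expect_identical(back$label, pt$label)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y,z", empty)
  expect_equal(nrow(read_points(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "1,2,3", "4,oops,6"), bad)
  err <- expect_error(read_points(bad), class = "synquant_parse_error")
  expect_match(conditionMessage(err), "row 2")

  noz <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2"), noz)
  expect_error(read_points(noz), class = "synquant_schema_error")
})

test_that("meshes round trip through PLY and OBJ with exact counts", {
  tetra <- surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  for (ext in c(".ply", ".obj")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(tetra, path)
    back <- read_mesh(path)
    expect_equal(nrow(back$vertices), 4L)
    expect_equal(nrow(back$faces), 4L)
    expect_equal(back$vertices, tetra$vertices)
    expect_equal(back$faces, tetra$faces)
  }
})

test_that("a loaded closed triangulation satisfies V - E + F = 2", {
  set.seed(3)
  u <- matrix(rnorm(900), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 100
  sph <- build_mesh(u, target_faces = 1000)
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(sph, path)
  back <- read_mesh(path)
  expect_equal(euler_characteristic(back), 2L)
})

test_that("zero-area faces are cleaned with a warning", {
  expect_warning(
    m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0)),
                      rbind(c(1, 2, 3), c(1, 2, 4))),  # second is collinear
    "zero-area")
  expect_equal(nrow(m$faces), 1L)
})

test_that("quads are fan-triangulated or rejected per flag", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3"), path)
  m <- read_mesh(path, triangulate = TRUE)
  expect_equal(nrow(m$faces), 2L)
  expect_error(read_mesh(path, triangulate = FALSE),
               class = "synquant_format_error")
})
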