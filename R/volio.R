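# Volume, point-table and mesh I/O with explicit unit conventions.
#
# Conventions fixed here and used by the whole pipeline:
#   * the internal length unit is nanometres everywhere; Angstrom appears
#     only inside MRC headers (pixel size = 10 x voxel_size)
#   * voxel indices are 0-based, coordinates refer to voxel centres
#   * on disk MRC data are stored x-fastest; the in-memory grid is an R
#     array indexed grid[x, y, z]
#   * the pipeline operates on "density-positive" volumes (membrane = local
#     intensity maximum); use invert = TRUE at load time for maps where
#     protein is dark.

#' Construct a tomogram object
#'
#' @param grid 3D numeric array of density, indexed `[x, y, z]`.
#' @param voxel_size isotropic voxel size in nm.
#' @param origin nm offset of the centre of voxel (0,0,0), length 3.
#' @param density_sign `"positive"` if larger values mean more mass.
#' @return an object of class `tomogram`.
#' @export
tomogram <- function(grid, voxel_size, origin = c(0, 0, 0),
                     density_sign = "positive") {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3L || any(dim(grid) < 1L)) {
    stop_synquant("grid must be a 3D array with positive dimensions",
                  "synquant_input_error")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop_synquant("voxel_size must be a single positive number (nm)",
                  "synquant_unit_error")
  }
  if (!all(is.finite(grid))) {
    stop_synquant("grid contains non-finite values", "synquant_input_error")
  }
  structure(
    list(grid = grid, voxel_size = voxel_size,
         origin = as.numeric(origin),
         density_sign = match.arg(density_sign, c("positive", "negative"))),
    class = "tomogram"
  )
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<tomogram> %d x %d x %d voxels, %.4f nm/voxel (%s density)\n",
              d[1], d[2], d[3], x$voxel_size, x$density_sign))
  invisible(x)
}

# -- MRC2014 ------------------------------------------------------------------

mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read an MRC2014 volume
#'
#' Reads a 3D MRC2014 file into a [tomogram]. The header pixel size (Angstrom)
#' is converted to nm. Mode 0 (int8), 1 (int16), 2 (float32) and 6 (uint16)
#' volumes are supported; only little-endian files are handled.
#'
#' @param path path to an `.mrc` file.
#' @param invert if `TRUE`, negate intensities at load (for maps in which
#'   protein is dark, as in raw cryoET contrast).
#' @return a [tomogram] with `voxel_size` in nm.
#' @export
read_volume <- function(path, invert = FALSE) {
  if (!file.exists(path)) {
    stop_synquant(paste0("no such file: ", path), "synquant_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  h_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- h_int[1]; ny <- h_int[2]; nz <- h_int[3]; mode <- h_int[4]
  mx <- h_int[8]; my <- h_int[9]; mz <- h_int[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 4 * 16)            # skip CELLB, jump to MAPC (word 17)
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  seek(con, 4 * 49)
  origin_a <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  map_tag <- rawToChar(readBin(con, "raw", n = 4))
  if (any(c(nx, ny, nz) <= 0) || !(as.character(mode) %in% names(mrc_modes)) ||
      any(c(mx, my, mz) <= 0) || map_tag != "MAP ") {
    stop_synquant("malformed MRC2014 header", "synquant_format_error")
  }
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    stop_synquant("only MAPC/MAPR/MAPS = 1,2,3 axis order is supported",
                  "synquant_format_error")
  }
  px <- cella / c(mx, my, mz)  # Angstrom per voxel on each axis
  if (any(px <= 0) || (max(px) - min(px)) / mean(px) > 0.01) {
    stop_synquant("anisotropic voxel size (>1% spread) is not supported",
                  "synquant_unit_error")
  }
  nsymbt <- {
    seek(con, 4 * 23)
    readBin(con, "integer", n = 1, size = 4, endian = "little")
  }
  seek(con, 1024 + nsymbt)
  n_vox <- nx * ny * nz
  vals <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n = n_vox, size = 1,
                             signed = TRUE, endian = "little")),
    `1` = as.numeric(readBin(con, "integer", n = n_vox, size = 2,
                             signed = TRUE, endian = "little")),
    `2` = readBin(con, "numeric", n = n_vox, size = 4, endian = "little"),
    `6` = as.numeric(readBin(con, "integer", n = n_vox, size = 2,
                             signed = FALSE, endian = "little"))
  )
  if (length(vals) != n_vox) {
    stop_synquant("truncated MRC data block", "synquant_format_error")
  }
  if (invert) vals <- -vals
  tomogram(array(vals, dim = c(nx, ny, nz)),
           voxel_size = mean(px) / 10,
           origin = origin_a / 10)
}

#' Write a tomogram as MRC2014 (mode 2, float32)
#'
#' The header pixel size is set to `voxel_size * 10` Angstrom. Float32 volumes
#' round-trip bit-exactly through [read_volume()].
#'
#' @param vol a [tomogram].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "tomogram"))
  d <- dim(vol$grid)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_synquant(
                    paste0("cannot open for writing: ", path),
                    "synquant_io_error"))
  on.exit(close(con))
  vals <- as.numeric(vol$grid)
  wr_i <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wr_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wr_i(c(d, 2L))                       # NX NY NZ MODE
  wr_i(c(0L, 0L, 0L))                  # NXSTART..
  wr_i(d)                              # MX MY MZ
  wr_f(d * vol$voxel_size * 10)        # CELLA (Angstrom)
  wr_f(c(90, 90, 90))                  # CELLB
  wr_i(c(1L, 2L, 3L))                  # MAPC MAPR MAPS
  wr_f(c(min(vals), max(vals), mean(vals)))  # DMIN DMAX DMEAN
  wr_i(c(0L, 0L))                      # ISPG NSYMBT
  wr_i(rep(0L, 2))                     # EXTRA[1:2]
  writeChar("MRCO", con, nchars = 4, eos = NULL)  # EXTTYP
  wr_i(20140L)                         # NVERSION
  wr_i(rep(0L, 21))                    # EXTRA[5:25]
  wr_f(vol$origin * 10)                # ORIGIN (Angstrom)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wr_f(stats::sd(vals))                # RMS
  wr_i(0L)                             # NLABL
  writeBin(raw(800), con)              # label block
  wr_f(vals)
  invisible(path)
}

# -- point tables -------------------------------------------------------------

point_labels <- c("PreSM", "PoSM", "receptor", "other")

#' Construct a point table
#'
#' @param coordinates numeric matrix (n x 3) of positions in nm.
#' @param label compartment tag, one of `"PreSM"`, `"PoSM"`, `"receptor"`,
#'   `"other"`; recycled to one per point.
#' @param source_voxel_size nm per voxel used if coordinates were converted
#'   from voxel units (`NA` when loaded directly in nm).
#' @return a `point_table` (a data.frame with columns x, y, z, label and an
#'   attribute `source_voxel_size`).
#' @export
point_table <- function(coordinates, label = "other", source_voxel_size = NA) {
  coordinates <- matrix(as.numeric(as.matrix(coordinates)), ncol = 3,
                        dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(coordinates) > 0 && !all(is.finite(coordinates))) {
    stop_synquant("coordinates must be finite", "synquant_input_error")
  }
  label <- as.character(label)
  if (!all(label %in% point_labels)) {
    stop_synquant(paste0("label must be one of: ",
                         paste(point_labels, collapse = ", ")),
                  "synquant_schema_error")
  }
  out <- data.frame(coordinates,
                    label = if (nrow(coordinates)) rep_len(label, nrow(coordinates))
                            else character(0))
  attr(out, "source_voxel_size") <- source_voxel_size
  class(out) <- c("point_table", "data.frame")
  out
}

#' Read a delimited point table
#'
#' Reads a comma- or tab-delimited text file with header columns `x,y,z` and
#' an optional `label` column. Coordinates are converted to nm exactly once:
#' with `units = "voxel"` each coordinate is multiplied by `voxel_size`; with
#' `units = "nm"` they are taken as-is regardless of `voxel_size`.
#'
#' @param path file path.
#' @param units `"nm"` or `"voxel"`.
#' @param voxel_size nm per voxel; required when `units = "voxel"`.
#' @param label default compartment label for files without a label column.
#' @return a [point_table] in nm.
#' @export
read_points <- function(path, units = c("nm", "voxel"), voxel_size = NULL,
                        label = "other") {
  units <- match.arg(units)
  if (!file.exists(path)) {
    stop_synquant(paste0("no such file: ", path), "synquant_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("x", "y", "z") %in% names(tab))) {
    stop_synquant("point table must have header columns x,y,z",
                  "synquant_schema_error")
  }
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop_synquant(sprintf("non-numeric value in column %s, data row %d",
                            col, bad[1]), "synquant_parse_error")
    }
    tab[[col]] <- v
  }
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  src <- NA
  if (units == "voxel") {
    if (is.null(voxel_size)) {
      stop_synquant("voxel units require an explicit voxel_size (nm)",
                    "synquant_unit_error")
    }
    xyz <- xyz * voxel_size
    src <- voxel_size
  }
  lab <- if ("label" %in% names(tab)) tab$label else label
  point_table(xyz, label = lab, source_voxel_size = src)
}

#' Write a point table as CSV (nm units)
#'
#' @param points a [point_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  df <- as.data.frame(points)
  lab <- if ("label" %in% names(df) && nrow(df)) df$label else character(nrow(df))
  lines <- c("x,y,z,label",
             if (nrow(df)) sprintf("%.17g,%.17g,%.17g,%s",
                                   df$x, df$y, df$z, lab))
  writeLines(lines, path)
  invisible(path)
}

# -- meshes -------------------------------------------------------------------

#' Construct a triangle mesh
#'
#' Degenerate (zero-area) faces are dropped with a warning at construction,
#' so every downstream edge weight is strictly positive.
#'
#' @param vertices numeric matrix (n x 3), nm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(as.matrix(vertices)), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop_synquant("face indices out of range", "synquant_input_error")
  }
  if (nrow(faces) > 0) {
    a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area2 <- sqrt(rowSums(cr^2))
    if (any(area2 <= 1e-12)) {
      warning(sprintf("dropping %d zero-area face(s)", sum(area2 <= 1e-12)))
      faces <- faces[area2 > 1e-12, , drop = FALSE]
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangle mesh (ASCII PLY or OBJ)
#'
#' @param path path ending in `.ply` or `.obj`.
#' @param triangulate if `TRUE`, quads and larger polygons are fan-
#'   triangulated; if `FALSE` they are rejected.
#' @return a [surface_mesh].
#' @export
read_mesh <- function(path, triangulate = TRUE) {
  if (!file.exists(path)) {
    stop_synquant(paste0("no such file: ", path), "synquant_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_ply(path, triangulate)
  else if (ext == "obj") read_obj(path, triangulate)
  else stop_synquant("mesh format must be .ply or .obj", "synquant_format_error")
}

fan_triangulate <- function(poly_list, triangulate) {
  out <- list()
  for (p in poly_list) {
    if (length(p) == 3L) {
      out[[length(out) + 1L]] <- p
    } else if (triangulate) {
      for (k in 2:(length(p) - 1L)) {
        out[[length(out) + 1L]] <- c(p[1], p[k], p[k + 1])
      }
    } else {
      stop_synquant("non-triangular face and triangulate = FALSE",
                    "synquant_format_error")
    }
  }
  do.call(rbind, out)
}

read_ply <- function(path, triangulate) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "ply") {
    stop_synquant("not a PLY file", "synquant_format_error")
  }
  end_hdr <- match("end_header", lines)
  hdr <- lines[seq_len(end_hdr)]
  if (!any(grepl("^format ascii", hdr))) {
    stop_synquant("only ASCII PLY is supported", "synquant_format_error")
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)[1]))
  if (is.na(nf)) nf <- 0L
  body <- lines[(end_hdr + 1L):length(lines)]
  vtx <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
  faces <- NULL
  if (nf > 0L) {
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    polys <- lapply(fl, function(x) {
      n <- as.integer(x[1])
      as.integer(x[1 + seq_len(n)]) + 1L  # PLY indices are 0-based
    })
    faces <- fan_triangulate(polys, triangulate)
  }
  surface_mesh(vtx, faces %||% matrix(integer(0), ncol = 3))
}

read_obj <- function(path, triangulate) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  vtx <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[2:4])))
  polys <- lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*", "", x[-1]))   # drop texture/normal refs
  })
  faces <- if (length(polys)) fan_triangulate(polys, triangulate)
           else matrix(integer(0), ncol = 3)
  surface_mesh(vtx, faces)
}

#' Write a triangle mesh (ASCII PLY or OBJ)
#'
#' @param mesh a [surface_mesh].
#' @param path output path ending in `.ply` or `.obj`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    vb <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    fb <- if (nrow(f)) sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L,
                               f[, 3] - 1L) else character(0)
    writeLines(c(hdr, vb, fb), path)
  } else if (ext == "obj") {
    vb <- sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    fb <- if (nrow(f)) sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
          else character(0)
    writeLines(c(vb, fb), path)
  } else {
    stop_synquant("mesh format must be .ply or .obj", "synquant_format_error")
  }
  invisible(path)
}
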