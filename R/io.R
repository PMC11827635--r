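#' Write a density grid as an MRC2014 map
#'
#' Minimal MRC2014 writer: mode 2 (32-bit IEEE float), little-endian, axis
#' order X fast / Y medium / Z slow matching the `values[ix, iy, iz]`
#' array layout, cell dimensions `dim * voxel_size`, and the grid origin in
#' the ORIGIN header words. Voxel data round-trip bit-exact; voxel size and
#' origin round-trip within 32-bit float representation.
#'
#' @param grid A [density_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(grid$values)
  writeBin(as.integer(c(d[1], d[2], d[3], 2L, 0L, 0L, 0L,
                        d[1], d[2], d[3])), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(d * grid$voxel_size, 90, 90, 90)), con, size = 4,
           endian = "little")                      # CELLA, CELLB
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  vals <- grid$values
  writeBin(as.numeric(c(min(vals), max(vals), mean(vals))), con, size = 4,
           endian = "little")                      # DMIN DMAX DMEAN
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")
  # EXTRA words 25-49; word 27 EXTTYP, word 28 NVERSION = 20140
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little")
  writeChar("MRCO", con, 4, eos = NULL)
  writeBin(as.integer(c(20140L, rep(0L, 21))), con, size = 4,
           endian = "little")
  writeBin(as.numeric(grid$origin), con, size = 4, endian = "little")
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  writeBin(as.numeric(stats::sd(vals)), con, size = 4, endian = "little")
  writeBin(1L, con, size = 4, endian = "little")    # NLABL
  lab <- sprintf("%-80s", "actinlattice synthetic map")
  writeChar(substr(lab, 1, 80), con, 80, eos = NULL)
  writeChar(paste(rep(" ", 720), collapse = ""), con, 720, eos = NULL)
  writeBin(as.numeric(grid$values), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 map into a density grid
#'
#' Supports mode 2 (32-bit float) volumes with the standard X/Y/Z axis
#' mapping. Malformed headers raise errors naming the offending field.
#'
#' @param path Path to an MRC file.
#' @return A [density_grid()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mxyz <- ints[8:10]
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))
  invisible(readBin(con, "integer", 2, size = 4, endian = "little"))
  invisible(readBin(con, "raw", 100))               # EXTRA
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  map_tag <- readChar(con, 4, useBytes = TRUE)
  if (!identical(map_tag, "MAP "))
    stop("malformed MRC header: MAP tag is '", map_tag, "'")
  if (nx <= 0 || ny <= 0 || nz <= 0)
    stop("malformed MRC header: non-positive dimensions NX/NY/NZ")
  if (mode != 2)
    stop("unsupported MRC mode ", mode, " (only mode 2, float32)")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order MAPC/MAPR/MAPS: ",
         paste(mapcrs, collapse = "/"))
  if (any(mxyz <= 0))
    stop("malformed MRC header: non-positive sampling MX/MY/MZ")
  seek(con, 1024)
  vals <- readBin(con, "numeric", nx * ny * nz, size = 4,
                  endian = "little")
  if (length(vals) < nx * ny * nz)
    stop("malformed MRC file: truncated data section")
  density_grid(array(vals, dim = c(nx, ny, nz)),
               voxel_size = cella / mxyz, origin = origin)
}

#' Write a filament model as a pose table
#'
#' CSV dialect: columns `index,strand,x,y,z,qw,qx,qy,qz` (Angstrom, unit
#' quaternions), dot decimal separator, one row per subunit.
#'
#' @param model A [filament_model()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_poses <- function(model, path) {
  stopifnot(inherits(model, "filament_model"))
  utils::write.csv(model$subunits, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a pose table into a filament model
#'
#' Rows are re-sorted by protomer index on read; missing columns raise a
#' format error naming them.
#'
#' @param path CSV path in the [write_poses()] dialect.
#' @return A [filament_model()].
#' @export
read_poses <- function(path) {
  df <- utils::read.csv(path)
  req <- c("index", "strand", "x", "y", "z", "qw", "qx", "qy", "qz")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("pose table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  filament_model(df)
}

#' Export a filament model as a pseudo-atom PDB
#'
#' One CA-like pseudo-atom per subunit centroid; chain A holds strand 0 and
#' chain B strand 1; residue numbers are `index + 1` (PDB residue numbering
#' is 1-based while protomer indices are 0-based).
#'
#' @param model A [filament_model()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
export_pdb <- function(model, path) {
  stopifnot(inherits(model, "filament_model"))
  s <- model$subunits
  lines <- vapply(seq_len(nrow(s)), function(i) {
    sprintf("ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, if (s$strand[i] == 0) "A" else "B", s$index[i] + 1,
            s$x[i], s$y[i], s$z[i], 1, 0)
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write / read a two-channel image pair as multi-page TIFF
#'
#' Channel A is page 1 and channel B page 2, stored as 32-bit float
#' samples scaled by `1 / scale` (float TIFF samples live in `[0, 1]`);
#' intensities round-trip within float32 representation for values below
#' `scale`. The pixel size and scale are not stored in the TIFF and must
#' be supplied on read.
#'
#' @param pair An [image_pair()].
#' @param path Output TIFF path.
#' @param scale Intensity divisor applied on write and reapplied on read.
#' @return `path`, invisibly.
#' @export
write_image_pair <- function(pair, path, scale = 65536) {
  stopifnot(inherits(pair, "image_pair"))
  if (max(pair$channel_a, pair$channel_b) > scale)
    stop("intensities exceed the storage scale; raise `scale`")
  tiff::writeTIFF(list(pair$channel_a / scale, pair$channel_b / scale),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_pair
#' @param pixel_size Pixel edge, um (not stored in the TIFF).
#' @return For `read_image_pair`: an [image_pair()].
#' @export
read_image_pair <- function(path, pixel_size = 0.1, scale = 65536) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2)
    stop("expected a two-page TIFF (channel A, channel B)")
  image_pair(pages[[1]] * scale, pages[[2]] * scale,
             pixel_size = pixel_size)
}

#' Write / read a lattice profile as CSV
#'
#' Columns `index,twist_deg,rise_ang,strand` plus a `step_kind` column;
#' locale-independent (dot decimal, fixed column order).
#'
#' @param profile A `lattice_profile`.
#' @param path CSV path.
#' @return `path`, invisibly; for `read_lattice_profile`, the profile.
#' @export
write_lattice_profile <- function(profile, path) {
  stopifnot(inherits(profile, "lattice_profile"))
  df <- cbind(profile$entries, step_kind = profile$step_kind)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lattice_profile
#' @export
read_lattice_profile <- function(path) {
  df <- utils::read.csv(path)
  req <- c("index", "twist_deg", "rise_ang", "strand", "step_kind")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("profile CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  new_lattice_profile(df[, c("index", "twist_deg", "rise_ang", "strand")],
                      unique(df$step_kind))
}
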