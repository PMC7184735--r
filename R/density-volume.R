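#' Density volume objects
#'
#' A `density_volume` wraps a 3D scalar field with a physical voxel size.
#' Data are stored as a numeric array indexed `[x, y, z]` (x fastest, the
#' native MRC layout); all physical coordinates are in nanometres, with the
#' centre of voxel `(1, 1, 1)` at `origin`.
#'
#' @param data numeric 3D array, indexed `[x, y, z]`.
#' @param voxel_size isotropic voxel edge length in nm (> 0).
#' @param origin nm coordinates `(x, y, z)` of the first voxel centre.
#' @return A `density_volume` object.
#' @export
density_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array indexed [x, y, z].")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    abort("`voxel_size` must be a single positive number (nm/voxel).")
  }
  if (any(dim(data) < 8L)) {
    abort("volume must have at least 8 voxels along each axis.")
  }
  structure(
    list(data = data, voxel_size = voxel_size, origin = as.numeric(origin)),
    class = "density_volume"
  )
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<density_volume> %d x %d x %d voxels @ %.3g nm/voxel (%.3g x %.3g x %.3g nm)\n",
    d[1], d[2], d[3], x$voxel_size,
    d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size
  ))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$data)

# Physical extent (nm) of the volume along each axis, measured voxel-centre
# to voxel-centre plus one voxel.
volume_extent_nm <- function(volume) dim(volume$data) * volume$voxel_size

#' Trilinear interpolation of a density volume
#'
#' Samples the volume at arbitrary physical points. Points falling outside
#' the voxel-centre bounding box are returned as `NA` (the caller decides
#' whether exclusion is an error).
#'
#' @param volume a [density_volume()].
#' @param points numeric matrix with columns `(x, y, z)` in nm.
#' @return numeric vector of interpolated densities, `NA` outside the volume.
#' @export
interp_volume <- function(volume, points) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  d <- dim(volume$data)
  # fractional 1-based voxel coordinates
  f <- sweep(points, 2L, volume$origin, "-") / volume$voxel_size + 1
  i0 <- floor(f)
  t <- f - i0
  ok <- i0[, 1] >= 1 & i0[, 1] + 1 <= d[1] &
    i0[, 2] >= 1 & i0[, 2] + 1 <= d[2] &
    i0[, 3] >= 1 & i0[, 3] + 1 <= d[3]
  out <- rep(NA_real_, nrow(points))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  t <- t[ok, , drop = FALSE]
  v <- volume$data
  corner <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  tx <- t[, 1]; ty <- t[, 2]; tz <- t[, 3]
  out[ok] <-
    corner(0, 0, 0) * (1 - tx) * (1 - ty) * (1 - tz) +
    corner(1, 0, 0) * tx * (1 - ty) * (1 - tz) +
    corner(0, 1, 0) * (1 - tx) * ty * (1 - tz) +
    corner(1, 1, 0) * tx * ty * (1 - tz) +
    corner(0, 0, 1) * (1 - tx) * (1 - ty) * tz +
    corner(1, 0, 1) * tx * (1 - ty) * tz +
    corner(0, 1, 1) * (1 - tx) * ty * tz +
    corner(1, 1, 1) * tx * ty * tz
  out
}

#' Read and write MRC volumes (mode 2, 32-bit float)
#'
#' Minimal MRC2014 support sufficient for exchanging density volumes with
#' tomography software: mode 2 data, standard 1024-byte header with the
#' `MAP ` stamp and cell dimensions encoding the voxel size.
#'
#' @param volume a [density_volume()].
#' @param path file path.
#' @return `read_mrc()` returns a [density_volume()]; `write_mrc()` returns
#'   `path` invisibly.
#' @export
write_mrc <- function(volume, path) {
  d <- dim(volume$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                        # nx ny nz
  wi(2L)                       # mode 2 = float32
  wi(c(0L, 0L, 0L))            # nxstart nystart nzstart
  wi(d)                        # mx my mz
  wf(d * volume$voxel_size * 10)  # cella in Angstrom
  wf(c(90, 90, 90))            # cellb
  wi(c(1L, 2L, 3L))            # mapc mapr maps
  rng <- range(volume$data)
  wf(c(rng[1], rng[2], mean(volume$data)))  # dmin dmax dmean
  wi(c(1L, 0L))                # ispg nsymbt
  writeBin(raw(100), con)      # extra
  wf(volume$origin * 10)       # origin (Angstrom)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(volume$data))          # rms
  wi(0L)                       # nlabl
  writeBin(raw(800), con)      # labels
  writeBin(as.numeric(volume$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) abort(sprintf("only MRC mode 2 (float32) is supported, got mode %d.", mode))
  ri(3L)              # nstart
  m <- ri(3L)
  cella <- rf(3L)
  rf(3L)              # cellb
  ri(3L)              # map order
  rf(3L)              # dmin dmax dmean
  ri(2L)              # ispg nsymbt
  readBin(con, "raw", n = 100L)
  origin <- rf(3L) / 10
  readBin(con, "raw", n = 4L)   # MAP stamp
  readBin(con, "raw", n = 4L)   # machine stamp
  rf(1L)              # rms
  ri(1L)
  readBin(con, "raw", n = 800L)
  data <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
  voxel <- cella[1] / 10 / m[1]
  density_volume(array(data, dim = d), voxel_size = voxel, origin = origin)
}
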