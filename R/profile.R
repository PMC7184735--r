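#' Membrane trace
#'
#' A set of model points following the inner membrane on a single 2D slice
#' of a tomogram, used to define the membrane frame for profile collapse.
#'
#' @param points data frame with nm columns `x`, `y`, `z` (>= 3 rows).
#' @param slice_axis which axis the slice holds fixed (`"x"`, `"y"` or `"z"`).
#' @return A `membrane_trace` object.
#' @export
membrane_trace <- function(points, slice_axis = "y") {
  points <- as_tibble(points)
  if (!all(c("x", "y", "z") %in% names(points))) {
    abort("`points` must have columns x, y, z (nm).")
  }
  if (nrow(points) < 3) abort("a membrane trace needs at least 3 points.")
  slice_axis <- match.arg(slice_axis, c("x", "y", "z"))
  structure(list(points = points[, c("x", "y", "z")], slice_axis = slice_axis),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("<membrane_trace> %d points on a %s slice\n",
              nrow(x$points), x$slice_axis))
  invisible(x)
}

#' Fit the membrane frame from a trace
#'
#' Estimates the in-slice membrane direction as the principal axis of the
#' trace points (largest variance, computed within the slice plane) and the
#' membrane normal as the in-slice perpendicular, unit length, oriented
#' towards the side flagged as cytoplasmic. The midplane point is the
#' centroid of the trace.
#'
#' @param trace a [membrane_trace()].
#' @param cytoplasm which half-space holds the cytoplasm, as a signed axis
#'   (`"+z"`, `"-z"`, `"+x"`, ...). The fitted normal points into it.
#' @return list with unit `normal`, `centroid` (nm) and in-plane unit
#'   vectors `u` (along the trace) and `v` (the slice axis).
#' @export
fit_membrane_frame <- function(trace, cytoplasm = "+z") {
  stopifnot(inherits(trace, "membrane_trace"))
  pts <- as.matrix(trace$points)
  centroid <- colMeans(pts)
  ax <- match(trace$slice_axis, c("x", "y", "z"))
  in_plane <- setdiff(1:3, ax)
  p2 <- sweep(pts[, in_plane, drop = FALSE], 2L, centroid[in_plane])
  cv <- crossprod(p2) / (nrow(p2) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (sqrt(max(eg$values)) < 1e-9) {
    abort("degenerate trace: points are coincident (no membrane direction).")
  }
  if (nrow(unique(round(p2, 9))) < 2) {
    abort("degenerate trace: points do not span the slice plane.")
  }
  dir2 <- eg$vectors[, 1]      # major axis, in-slice
  u <- numeric(3); u[in_plane] <- dir2
  v <- numeric(3); v[ax] <- 1
  normal <- c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  normal <- normal / sqrt(sum(normal^2))
  sign_axis <- match(substr(cytoplasm, 2, 2), c("x", "y", "z"))
  sgn <- if (substr(cytoplasm, 1, 1) == "-") -1 else 1
  if (normal[sign_axis] * sgn < 0) {
    normal <- -normal
    u <- -u
  }
  list(normal = normal, centroid = centroid, u = u, v = v)
}

#' Collapse a volume subsection into a 1D density profile
#'
#' Averages trilinearly interpolated densities over plane patches parallel
#' to the fitted membrane, one patch per bin along the membrane normal,
#' producing the 1D side-view profile used for layer metrology. Coordinate 0
#' is the membrane midplane (trace centroid); positive is the cytoplasmic
#' side. Sample points falling outside the volume are excluded; a bin left
#' with no samples is an error.
#'
#' @param volume a [density_volume()].
#' @param trace a [membrane_trace()].
#' @param extent_nm profile half-extent along the normal (bins span
#'   `[-extent_nm, +extent_nm]`).
#' @param lateral_halfwidth_nm half-width of the averaging patch around the
#'   trace centroid, in both in-plane directions.
#' @param bin_width_nm bin width along the normal.
#' @param cytoplasm signed axis naming the cytoplasmic side (see
#'   [fit_membrane_frame()]).
#' @param sample_pitch_nm spacing of the in-plane sampling grid; defaults to
#'   half the voxel size.
#' @return A `density_profile`: a tibble with columns `bin_center` (nm),
#'   `value` (mean density) and `count` (samples per bin), plus provenance
#'   in attribute `meta`.
#' @export
collapse_profile <- function(volume, trace, extent_nm,
                             lateral_halfwidth_nm = 8,
                             bin_width_nm = 1,
                             cytoplasm = "+z",
                             sample_pitch_nm = NULL) {
  stopifnot(inherits(volume, "density_volume"))
  if (extent_nm < bin_width_nm) {
    abort("`extent_nm` must cover at least 2 bins.")
  }
  frame <- fit_membrane_frame(trace, cytoplasm)
  pitch <- sample_pitch_nm %||% (volume$voxel_size / 2)
  centers <- seq(-extent_nm, extent_nm, by = bin_width_nm)
  lat <- seq(-lateral_halfwidth_nm, lateral_halfwidth_nm, by = pitch)
  patch <- as.matrix(expand.grid(a = lat, b = lat))
  base <- patch[, 1] %o% frame$u + patch[, 2] %o% frame$v
  base <- sweep(base, 2L, frame$centroid, "+")

  values <- numeric(length(centers))
  counts <- integer(length(centers))
  for (i in seq_along(centers)) {
    pts <- sweep(base, 2L, centers[i] * frame$normal, "+")
    s <- interp_volume(volume, pts)
    counts[i] <- sum(!is.na(s))
    if (counts[i] == 0L) {
      abort(sprintf("bin at %+.2f nm has no samples inside the volume; reduce `extent_nm` or the patch size.", centers[i]))
    }
    values[i] <- mean(s, na.rm = TRUE)
  }
  new_density_profile(
    tibble(bin_center = centers, value = values, count = counts),
    meta = list(
      extent_nm = extent_nm, bin_width_nm = bin_width_nm,
      lateral_halfwidth_nm = lateral_halfwidth_nm,
      sample_pitch_nm = pitch, cytoplasm = cytoplasm,
      normal = frame$normal, centroid = frame$centroid
    )
  )
}

new_density_profile <- function(df, meta = list()) {
  structure(as_tibble(df), meta = meta,
            class = c("density_profile", class(as_tibble(df))))
}

#' Profile JSON input/output
#'
#' Profiles are serialised as JSON objects with `bin_centers`, `values`,
#' `counts` and `meta` members.
#'
#' @param profile a `density_profile` from [collapse_profile()].
#' @param path file path.
#' @return `read_profile_json()` returns a `density_profile`;
#'   `write_profile_json()` returns `path` invisibly.
#' @export
write_profile_json <- function(profile, path) {
  meta <- attr(profile, "meta") %||% list()
  jsonlite::write_json(
    list(bin_centers = profile$bin_center, values = profile$value,
         counts = profile$count, meta = meta),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_density_profile(
    tibble(bin_center = obj$bin_centers, value = obj$values,
           count = obj$counts),
    meta = as.list(obj$meta)
  )
}

#' Trace input/output
#'
#' Traces are written either as JSON or as IMOD-style text (one `x y z`
#' per line, nm units).
#'
#' @param trace a [membrane_trace()].
#' @param path file path.
#' @param format `"json"` or `"imod"`.
#' @return `read_trace()` returns a [membrane_trace()].
#' @export
write_trace <- function(trace, path, format = c("json", "imod")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(points = trace$points, slice_axis = trace$slice_axis),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    writeLines(sprintf("%.6g %.6g %.6g",
                       trace$points$x, trace$points$y, trace$points$z), path)
  }
  invisible(path)
}

#' @rdname write_trace
#' @param slice_axis slice axis for IMOD-format input (JSON stores its own).
#' @export
read_trace <- function(path, format = c("json", "imod"), slice_axis = "y") {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    membrane_trace(as_tibble(obj$points), slice_axis = obj$slice_axis)
  } else {
    m <- utils::read.table(path, col.names = c("x", "y", "z"))
    membrane_trace(as_tibble(m), slice_axis = slice_axis)
  }
}
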