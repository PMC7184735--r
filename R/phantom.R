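#' Specification for a membrane/layer phantom volume
#'
#' Describes the geometry of a synthetic chemosensory-array side view: an
#' inner membrane (rendered as two parallel Gaussian sheets 4 nm apart, the
#' bilayer leaflets; the recorded truth is their midplane), a CheA/CheW
#' baseplate sheet `baseplate_offset` nm on the cytoplasmic side of the
#' membrane midplane, and intermediate density layers each placed
#' `layer_offsets[i]` nm above the baseplate, back towards the membrane.
#' Higher voxel values mean more mass.
#'
#' @param dims voxel counts `(z, y, x)`.
#' @param voxel_size nm per voxel (isotropic).
#' @param membrane_position nm position of the membrane midplane along z.
#' @param baseplate_offset nm from membrane midplane to the baseplate sheet
#'   (cytoplasm is the +z side).
#' @param layer_offsets strictly increasing nm offsets of intermediate layers
#'   above (towards the membrane from) the baseplate.
#' @param layer_amplitudes peak density of each layer sheet (recycled).
#' @param layer_sigma Gaussian sheet width (nm) of the baseplate and layer
#'   sheets.
#' @param membrane_sigma Gaussian sheet width (nm) of the membrane leaflet
#'   sheets (lipid leaflets image sharper than protein layers).
#' @param membrane_amplitude,baseplate_amplitude peak densities of the
#'   membrane leaflet sheets and the baseplate sheet.
#' @param noise_sigma sd of additive Gaussian voxel noise (density units).
#' @param tilt_degrees membrane tilt about the y axis (degrees).
#' @param seed integer seed controlling the noise draw.
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(dims = c(96, 48, 48),
                         voxel_size = 1,
                         membrane_position = 20,
                         baseplate_offset = 37,
                         layer_offsets = numeric(),
                         layer_amplitudes = 0.5,
                         layer_sigma = 2,
                         membrane_sigma = 1.2,
                         membrane_amplitude = 1,
                         baseplate_amplitude = 0.8,
                         noise_sigma = 0,
                         tilt_degrees = 0,
                         seed = 1L) {
  if (voxel_size <= 0) abort("`voxel_size` must be > 0.")
  if (layer_sigma <= 0) abort("`layer_sigma` must be > 0.")
  if (membrane_sigma <= 0) abort("`membrane_sigma` must be > 0.")
  z_extent <- dims[1] * voxel_size
  if (membrane_position < 0 || membrane_position >= z_extent) {
    abort("`membrane_position` must lie inside the volume.")
  }
  if (baseplate_offset < 0 || membrane_position + baseplate_offset >= z_extent) {
    abort("baseplate falls outside the volume.")
  }
  if (length(layer_offsets)) {
    if (any(diff(layer_offsets) <= 0)) {
      abort("`layer_offsets` must be strictly increasing.")
    }
    bad <- layer_offsets[layer_offsets < 0 | layer_offsets >= baseplate_offset]
    if (length(bad)) {
      abort(sprintf(
        "layer offset %s nm falls outside the membrane-baseplate span (%g nm).",
        paste(bad, collapse = ", "), baseplate_offset
      ))
    }
  }
  layer_amplitudes <- rep_len(layer_amplitudes, length(layer_offsets))
  structure(
    list(
      dims = as.integer(dims), voxel_size = voxel_size,
      membrane_position = membrane_position,
      baseplate_offset = baseplate_offset,
      layer_offsets = as.numeric(layer_offsets),
      layer_amplitudes = layer_amplitudes,
      layer_sigma = layer_sigma,
      membrane_sigma = membrane_sigma,
      membrane_amplitude = membrane_amplitude,
      baseplate_amplitude = baseplate_amplitude,
      noise_sigma = noise_sigma,
      tilt_degrees = tilt_degrees,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# nm distance between the two membrane leaflet sheets
MEMBRANE_LEAFLET_GAP <- 4

#' Generate a membrane/layer phantom volume with ground truth
#'
#' Builds a [density_volume()] containing Gaussian density sheets for the
#' membrane leaflets, the CheA/CheW baseplate and each intermediate layer,
#' plus seeded additive Gaussian noise, together with a machine-readable
#' ground-truth record and a membrane trace usable by [collapse_profile()].
#' Identical specs (same seed) give bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @param n_trace_points number of trace points placed along the membrane
#'   midplane on the central y slice.
#' @return A list with elements `volume` ([density_volume()]), `trace`
#'   ([membrane_trace()]) and `truth` (list of exact sheet geometry: nm
#'   offsets of every sheet from the membrane midplane along the normal,
#'   and the layer offsets above the baseplate).
#' @export
gen_layer_volume <- function(spec, n_trace_points = 9) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$dims[3]; ny <- spec$dims[2]; nz <- spec$dims[1]
  vs <- spec$voxel_size
  theta <- spec$tilt_degrees * pi / 180
  cx <- (nx - 1) / 2 * vs
  x <- (seq_len(nx) - 1) * vs
  z <- (seq_len(nz) - 1) * vs

  # signed distance of each (x, z) voxel centre from the tilted membrane
  # midplane; the cytoplasmic (+) side is towards +z
  n_vec <- c(sin(theta), 0, cos(theta))
  dmat <- outer(x - cx, rep(1, nz)) * n_vec[1] +
    outer(rep(1, nx), z - spec$membrane_position) * n_vec[3]

  sheet_offsets <- c(
    -MEMBRANE_LEAFLET_GAP / 2, MEMBRANE_LEAFLET_GAP / 2,
    spec$baseplate_offset,
    if (length(spec$layer_offsets)) spec$baseplate_offset - spec$layer_offsets
  )
  sheet_amps <- c(
    spec$membrane_amplitude, spec$membrane_amplitude,
    spec$baseplate_amplitude,
    spec$layer_amplitudes
  )
  sheet_sigmas <- c(spec$membrane_sigma, spec$membrane_sigma,
                    rep(spec$layer_sigma, length(sheet_offsets) - 2L))
  plane <- matrix(0, nx, nz)
  for (s in seq_along(sheet_offsets)) {
    plane <- plane + sheet_amps[s] *
      exp(-(dmat - sheet_offsets[s])^2 / (2 * sheet_sigmas[s]^2))
  }
  data <- aperm(array(plane, dim = c(nx, nz, ny)), c(1, 3, 2))
  if (spec$noise_sigma > 0) {
    data <- data + withr::with_seed(
      spec$seed,
      array(rnorm(nx * ny * nz, sd = spec$noise_sigma), dim = c(nx, ny, nz))
    )
  }
  volume <- density_volume(data, voxel_size = vs)

  # trace points follow the membrane midplane on the central y slice
  y_mid <- (ny - 1) / 2 * vs
  tx <- seq(cx - (nx - 1) * vs / 4, cx + (nx - 1) * vs / 4,
            length.out = n_trace_points)
  tz <- spec$membrane_position - tan(theta) * (tx - cx)
  trace <- membrane_trace(
    tibble(x = tx, y = y_mid, z = tz),
    slice_axis = "y"
  )

  truth <- list(
    membrane_midplane_nm = 0,
    leaflet_offsets_nm = c(-MEMBRANE_LEAFLET_GAP / 2, MEMBRANE_LEAFLET_GAP / 2),
    baseplate_nm = spec$baseplate_offset,
    layer_positions_nm = if (length(spec$layer_offsets)) {
      spec$baseplate_offset - spec$layer_offsets
    } else numeric(),
    layer_offsets_above_baseplate_nm = spec$layer_offsets,
    normal = n_vec,
    spec = spec
  )
  list(volume = volume, trace = trace, truth = truth)
}

#' Generate a hexagonal receptor-lattice top view
#'
#' Places Gaussian spots on a hexagonal lattice with the given spacing, at a
#' seeded random orientation and phase, plus additive Gaussian noise. This
#' emulates a top view of the receptor packing at the baseplate.
#'
#' @param spacing_nm nearest-neighbour lattice spacing (nm).
#' @param pixel_size_nm nm per pixel.
#' @param dims image size in pixels `(rows, cols)`.
#' @param spot_sigma Gaussian spot width (nm); must satisfy
#'   `spacing_nm > 2 * spot_sigma`.
#' @param amplitude spot peak value; `0` gives a lattice-free noise image.
#' @param noise_sigma sd of additive Gaussian pixel noise.
#' @param seed integer seed (orientation, phase and noise).
#' @return A numeric matrix with attributes `pixel_size_nm` and `truth`
#'   (lattice spacing, orientation and site coordinates in nm).
#' @export
gen_hex_lattice <- function(spacing_nm, pixel_size_nm = 1, dims = c(128, 128),
                            spot_sigma = 2, amplitude = 1, noise_sigma = 0,
                            seed = 1L) {
  if (spacing_nm <= 2 * spot_sigma) {
    abort("`spacing_nm` must exceed 2 * spot_sigma for spots to be resolved.")
  }
  if (spacing_nm / pixel_size_nm < 3) {
    abort("lattice spacing is not resolvable at this pixel size (< 3 px).")
  }
  nr <- dims[1]; nc <- dims[2]
  withr::with_seed(seed, {
    theta <- runif(1, 0, pi / 3)
    phase <- runif(2, 0, spacing_nm)
    img <- matrix(0, nr, nc)
    sites <- NULL
    if (amplitude > 0) {
      a1 <- spacing_nm * c(cos(theta), sin(theta))
      a2 <- spacing_nm * c(cos(theta + pi / 3), sin(theta + pi / 3))
      w <- max(nr, nc) * pixel_size_nm
      mrange <- ceiling(w / spacing_nm) + 2
      grid <- expand.grid(m = -mrange:mrange, n = -mrange:mrange)
      sx <- grid$m * a1[1] + grid$n * a2[1] + phase[1]
      sy <- grid$m * a1[2] + grid$n * a2[2] + phase[2]
      pad <- 4 * spot_sigma
      keep <- sx > -pad & sx < nc * pixel_size_nm + pad &
        sy > -pad & sy < nr * pixel_size_nm + pad
      sites <- cbind(x = sx[keep], y = sy[keep])
      px <- (seq_len(nc) - 1) * pixel_size_nm
      py <- (seq_len(nr) - 1) * pixel_size_nm
      half <- ceiling(4 * spot_sigma / pixel_size_nm)
      for (s in seq_len(nrow(sites))) {
        ic <- round(sites[s, "x"] / pixel_size_nm) + 1
        jc <- round(sites[s, "y"] / pixel_size_nm) + 1
        if (ic + half < 1 || ic - half > nc || jc + half < 1 || jc - half > nr) next
        ii <- max(1, ic - half):min(nc, ic + half)
        jj <- max(1, jc - half):min(nr, jc + half)
        gx <- exp(-(px[ii] - sites[s, "x"])^2 / (2 * spot_sigma^2))
        gy <- exp(-(py[jj] - sites[s, "y"])^2 / (2 * spot_sigma^2))
        img[jj, ii] <- img[jj, ii] + amplitude * outer(gy, gx)
      }
    }
    if (noise_sigma > 0) {
      img <- img + matrix(rnorm(nr * nc, sd = noise_sigma), nr, nc)
    }
    structure(
      img,
      pixel_size_nm = pixel_size_nm,
      truth = list(spacing_nm = if (amplitude > 0) spacing_nm else NA_real_,
                   orientation_rad = theta,
                   sites_nm = sites)
    )
  })
}
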