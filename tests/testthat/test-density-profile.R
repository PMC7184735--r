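test_that("membrane frame recovers axis-aligned and tilted plane normals", {
  tr <- membrane_trace(
    tibble::tibble(x = seq(10, 40, 5), y = 25, z = 50), slice_axis = "y"
  )
  fr <- fit_membrane_frame(tr, cytoplasm = "+z")
  expect_equal(fr$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(unname(fr$centroid[3]), 50)

  theta <- 30 * pi / 180
  xs <- seq(-20, 20, 4)
  tr2 <- membrane_trace(
    tibble::tibble(x = xs + 30, y = 12, z = 50 - tan(theta) * xs),
    slice_axis = "y"
  )
  fr2 <- fit_membrane_frame(tr2, cytoplasm = "+z")
  analytic <- c(sin(theta), 0, cos(theta))
  angle <- acos(min(1, sum(fr2$normal * analytic)))
  expect_lt(angle, 1e-6)
})

test_that("degenerate traces are rejected", {
  expect_error(
    membrane_trace(tibble::tibble(x = c(1, 2), y = 0, z = 0)),
    "at least 3"
  )
  expect_error(
    fit_membrane_frame(membrane_trace(
      tibble::tibble(x = c(5, 5, 5), y = 1, z = c(7, 7, 7))
    )),
    "degenerate"
  )
})

test_that("collapse of a constant volume is constant for any geometry", {
  vol <- density_volume(array(3.25, dim = c(32, 32, 32)), voxel_size = 1)
  tr <- membrane_trace(
    tibble::tibble(x = seq(8, 24, 2), y = 15,
                   z = 16 - 0.3 * (seq(8, 24, 2) - 16)),
    slice_axis = "y"
  )
  pr <- collapse_profile(vol, tr, extent_nm = 6, lateral_halfwidth_nm = 4,
                         bin_width_nm = 1)
  expect_true(all(abs(pr$value - 3.25) < 1e-12))
  expect_true(all(pr$count > 0))
})

test_that("axis-aligned collapse equals the plane-by-plane voxel means", {
  spec <- layered_phantom_spec(noise_sigma = 0.3, seed = 11)
  ph <- gen_layer_volume(spec)
  pr <- collapse_profile(ph$volume, ph$trace, extent_nm = 40,
                         lateral_halfwidth_nm = 6, bin_width_nm = 1)
  # oracle: mean over each z voxel plane restricted to the sampled patch
  frame <- fit_membrane_frame(ph$trace)
  lat <- seq(-6, 6, by = 0.5)
  for (b in c(-20, 0, 10, 37)) {
    z_idx <- round(46 + b) + 1L
    xs <- frame$centroid[1] + lat
    ys <- frame$centroid[2] + lat
    # direct per-point sampling oracle on the exact voxel plane
    pts <- as.matrix(expand.grid(x = xs, y = ys))
    vals <- apply(pts, 1, function(p) {
      x0 <- floor(p[1]) + 1L; y0 <- floor(p[2]) + 1L
      tx <- p[1] - (x0 - 1); ty <- p[2] - (y0 - 1)
      v <- ph$volume$data
      v[x0, y0, z_idx] * (1 - tx) * (1 - ty) +
        v[x0 + 1L, y0, z_idx] * tx * (1 - ty) +
        v[x0, y0 + 1L, z_idx] * (1 - tx) * ty +
        v[x0 + 1L, y0 + 1L, z_idx] * tx * ty
    })
    expect_equal(pr$value[pr$bin_center == b], mean(vals), tolerance = 1e-9)
  }
  # noise-free, the sheet value is constant across each plane, so the
  # profile equals the straight voxel-plane mean exactly
  ph0 <- gen_layer_volume(layered_phantom_spec(noise_sigma = 0))
  pr0 <- collapse_profile(ph0$volume, ph0$trace, extent_nm = 40,
                          lateral_halfwidth_nm = 6, bin_width_nm = 1)
  for (b in c(-10, 0, 20, 37)) {
    z_idx <- round(46 + b) + 1L
    expect_equal(pr0$value[pr0$bin_center == b],
                 mean(ph0$volume$data[, , z_idx]), tolerance = 1e-9)
  }
})

test_that("a single sheet collapses to a peak at its true offset", {
  spec <- phantom_spec(
    dims = c(64, 24, 24), membrane_position = 30, baseplate_offset = 25,
    membrane_amplitude = 0, baseplate_amplitude = 0,
    layer_offsets = 15, layer_amplitudes = 1, layer_sigma = 2
  )
  # single sheet at 25 - 15 = +10 nm from the midplane
  ph <- gen_layer_volume(spec)
  pr <- collapse_profile(ph$volume, ph$trace, extent_nm = 20,
                         bin_width_nm = 1)
  expect_equal(pr$bin_center[which.max(pr$value)], 10)
})

test_that("bins falling wholly outside the volume are an error", {
  vol <- density_volume(array(1, dim = c(16, 16, 16)), voxel_size = 1)
  tr <- membrane_trace(tibble::tibble(x = seq(4, 12, 2), y = 8, z = 8))
  expect_error(collapse_profile(vol, tr, extent_nm = 30), "no samples")
})

test_that("peak detection refines an exact parabola with zero uncertainty", {
  x <- 0:30
  y <- 5 - 0.05 * (x - 17)^2
  pk <- detect_peaks(tibble::tibble(bin_center = x, value = y),
                     min_prominence = 0.1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$center, 17, tolerance = 1e-9)
  expect_lt(pk$standard_uncertainty, 1e-12)
  expect_lt(pk$expanded_uncertainty, 1e-12)
  expect_equal(pk$k, 2)
})

test_that("flat profiles yield no peaks and non-finite profiles error", {
  flat <- tibble::tibble(bin_center = 0:10, value = rep(1, 11))
  expect_equal(nrow(detect_peaks(flat, 0.01)), 0L)
  bad <- tibble::tibble(bin_center = 0:10, value = c(rep(1, 10), NA))
  expect_error(detect_peaks(bad, 0.01), "non-finite")
  expect_error(detect_peaks(tibble::tibble(bin_center = 0:3, value = 1:4 * 1.0)),
               "5 bins")
})

test_that("sub-bin Gaussian centres are recovered with calibrated coverage", {
  x <- 0:40
  true_center <- 17.3
  clean <- exp(-(x - true_center)^2 / (2 * 2^2))
  res <- withr::with_seed(42, {
    t(replicate(200, {
      y <- clean + rnorm(length(x), sd = 0.02)
      pk <- detect_peaks(tibble::tibble(bin_center = x, value = y),
                         min_prominence = 0.5)
      apex <- pk[which.max(pk$height), ]
      c(center = apex$center, exp_u = apex$expanded_uncertainty)
    }))
  })
  expect_lt(abs(mean(res[, "center"]) - true_center), 0.1)
  coverage <- mean(abs(res[, "center"] - true_center) <= res[, "exp_u"])
  expect_gte(coverage, 0.9)
})

test_that("reported uncertainty does not decrease with noise", {
  x <- 0:40
  clean <- exp(-(x - 20)^2 / 8)
  mean_u <- vapply(c(0.005, 0.02, 0.08), function(ns) {
    withr::with_seed(99, {
      mean(replicate(50, {
        y <- clean + rnorm(length(x), sd = ns)
        pk <- detect_peaks(tibble::tibble(bin_center = x, value = y), 0.5)
        pk$standard_uncertainty[which.max(pk$height)]
      }))
    })
  }, numeric(1))
  expect_true(all(diff(mean_u) > 0))
})

test_that("layer distances and uncertainties combine as k*sqrt(u^2+u_ref^2)", {
  pk <- tibble::tibble(
    center = c(0, 17.5), height = c(1, 0.5), prominence = c(1, 0.5),
    standard_uncertainty = c(0.5, 0.56),
    expanded_uncertainty = 2 * c(0.5, 0.56), k = 2,
    label = c("AW", "L1")
  )
  rep <- measure_layers(pk, "AW")
  expect_equal(rep$distances$distance_nm, 17.5)
  expect_equal(rep$distances$expanded_uncertainty_nm,
               2 * sqrt(0.5^2 + 0.56^2))
  expect_equal(round(rep$distances$expanded_uncertainty_nm, 1), 1.5)

  # coincident peaks: distance 0, uncertainty k*sqrt(2)*u
  pk2 <- pk; pk2$center <- c(5, 5); pk2$standard_uncertainty <- c(0.3, 0.3)
  rep2 <- measure_layers(pk2, "AW")
  expect_equal(rep2$distances$distance_nm, 0)
  expect_equal(rep2$distances$expanded_uncertainty_nm, 2 * sqrt(2) * 0.3)

  # exact distances with zero uncertainty
  pk3 <- tibble::tibble(
    center = c(0, 10, 20), height = 1, prominence = 1,
    standard_uncertainty = 0, expanded_uncertainty = 0, k = 2,
    label = c("AW", "a", "b")
  )
  rep3 <- measure_layers(pk3, "AW")
  expect_equal(sort(rep3$distances$distance_nm), c(10, 20))
  expect_equal(rep3$distances$expanded_uncertainty_nm, c(0, 0))

  expect_error(measure_layers(pk3, "missing"), "exactly once")
})

test_that("peak labelling merges the bilayer and orders layers from AW", {
  pk <- tibble::tibble(
    center = c(-2, 2, 6.9, 12.5, 19.5, 37),
    height = c(1, 1, 0.5, 0.5, 0.5, 0.8), prominence = 0.5,
    standard_uncertainty = 0.1, expanded_uncertainty = 0.2, k = 2,
    label = NA_character_
  )
  lab <- label_peaks(pk)
  expect_equal(nrow(lab), 5L)  # leaflets merged
  expect_equal(lab$center[lab$label == "IM"], 0)
  expect_equal(lab$center[lab$label == "AW"], 37)
  expect_equal(lab$center[lab$label == "L1"], 19.5)
  expect_equal(lab$center[lab$label == "L3"], 6.9)
  expect_equal(lab$standard_uncertainty[lab$label == "IM"],
               sqrt(2 * 0.1^2) / 2)
})

test_that("pooling follows mean and sqrt(sum u^2)/n propagation", {
  m4 <- tibble::tibble(value = rep(17.5, 4), expanded_uncertainty = 1.5, k = 2)
  p4 <- pool_measurements(m4)
  expect_equal(p4$mean, 17.5)
  expect_equal(p4$expanded_uncertainty, 0.75)

  m1 <- tibble::tibble(value = 10, expanded_uncertainty = 0.8, k = 2)
  p1 <- pool_measurements(m1)
  expect_equal(p1$mean, 10)
  expect_equal(p1$expanded_uncertainty, 0.8)

  m2 <- tibble::tibble(value = c(10, 20), expanded_uncertainty = c(1, 1), k = 2)
  p2 <- pool_measurements(m2)
  expect_equal(p2$mean, 15)
  expect_equal(p2$expanded_uncertainty, sqrt(2) / 2, tolerance = 1e-12)

  bad <- tibble::tibble(value = c(1, 2), expanded_uncertainty = 1, k = c(2, 3))
  expect_error(pool_measurements(bad), "coverage factor")
})

test_that("lattice spacing is recovered, refused on noise, and scale-equivariant", {
  img <- gen_hex_lattice(12, 1, c(128, 128), 2, noise_sigma = 0, seed = 3)
  est <- estimate_lattice_spacing(img)
  expect_true(est$detected)
  expect_lt(abs(est$spacing_nm - 12), 0.2)

  noise <- gen_hex_lattice(12, 1, c(128, 128), 2, amplitude = 0,
                           noise_sigma = 0.5, seed = 4)
  expect_false(estimate_lattice_spacing(noise)$detected)

  half <- gen_hex_lattice(6, 0.5, c(128, 128), 1, noise_sigma = 0, seed = 3)
  est_half <- estimate_lattice_spacing(half, 0.5)
  expect_equal(est_half$spacing_nm / est$spacing_nm, 0.5, tolerance = 0.02)

  expect_error(estimate_lattice_spacing(matrix(0, 32, 32), 1), "64 x 64")
})

test_that("rigid motion of volume and trace leaves distances unchanged", {
  run <- function(tilt) {
    measure_phantom(layered_phantom_spec(tilt = tilt, dims = c(96, 48, 48)))
  }
  a <- run(0); b <- run(20)
  for (lbl in c("IM", "L1", "L2", "L3")) {
    expect_lt(abs(a$distance_nm[a$label == lbl] -
                    b$distance_nm[b$label == lbl]), 0.25)
  }
})
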