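#' Detect peaks in a 1D density profile
#'
#' Finds local maxima (optionally after inverting the profile, for data
#' where protein is dark) with at least the requested prominence and mutual
#' separation. Each peak centre is refined by a three-point parabola through
#' the apex bin and its neighbours; its standard uncertainty is the
#' propagation of the profile's residual-noise estimate (median absolute
#' second difference) through the parabola apex formula, expanded with
#' coverage factor `k`.
#'
#' @param profile a `density_profile` (or any data frame with `bin_center`
#'   and `value` columns).
#' @param min_prominence minimum peak prominence, in density units.
#' @param min_separation_nm minimum separation between reported peaks; when
#'   two candidates are closer, the higher one wins.
#' @param invert logical; invert the profile before peak finding.
#' @param k coverage factor for expanded uncertainties (default 2).
#' @return A tibble of peak measurements: `center`, `height`, `prominence`,
#'   `standard_uncertainty`, `expanded_uncertainty`, `k`, `label` (`NA`,
#'   fill with [label_peaks()]).
#' @export
detect_peaks <- function(profile, min_prominence = 0.1,
                         min_separation_nm = 0, invert = FALSE, k = 2) {
  x <- profile$bin_center
  y <- profile$value
  if (length(y) < 5) abort("profile must have at least 5 bins.")
  if (any(!is.finite(y))) abort("profile contains non-finite values.")
  if (invert) y <- -y
  n <- length(y)
  bin_width <- x[2] - x[1]

  # local maxima (plateaus take their first bin)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(is_max)) return(empty_peaks(k))

  prominence <- vapply(is_max, function(i) {
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > y[i])
    min_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):(i - 1)]) else min(left)
    right <- y[(i + 1):n]
    higher_r <- which(right > y[i])
    min_r <- if (length(higher_r)) min(y[(i + 1):(i + min(higher_r) - 1)]) else min(right)
    y[i] - max(min_l, min_r)
  }, numeric(1))

  keep <- prominence >= min_prominence
  is_max <- is_max[keep]
  prominence <- prominence[keep]
  if (!length(is_max)) return(empty_peaks(k))

  # enforce separation, highest first
  ord <- order(y[is_max], decreasing = TRUE)
  chosen <- integer()
  for (i in ord) {
    if (!length(chosen) ||
        all(abs(x[is_max[i]] - x[is_max[chosen]]) >= min_separation_nm)) {
      chosen <- c(chosen, i)
    }
  }
  is_max <- is_max[sort(chosen)]
  prominence <- prominence[sort(chosen)]

  noise <- mad(diff(y, differences = 2)) / sqrt(6)

  refine <- function(i) {
    if (i <= 1L || i >= n) {
      return(c(center = x[i], height = y[i], u = NA_real_))
    }
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom >= 0) {
      return(c(center = x[i], height = y2, u = NA_real_))
    }
    delta <- 0.5 * (y1 - y3) / denom
    center <- x[i] + delta * bin_width
    height <- y2 - 0.25 * (y1 - y3) * delta
    # gradient of delta wrt (y1, y2, y3) for noise propagation
    num <- y1 - y3
    g1 <- (denom - num) / (2 * denom^2)
    g2 <- num / denom^2
    g3 <- -(denom + num) / (2 * denom^2)
    u <- noise * sqrt(g1^2 + g2^2 + g3^2) * bin_width
    c(center = center, height = height, u = u)
  }
  ref <- t(vapply(is_max, refine, numeric(3)))
  sign_fix <- if (invert) -1 else 1
  tibble(
    center = unname(ref[, "center"]),
    height = sign_fix * unname(ref[, "height"]),
    prominence = unname(prominence),
    standard_uncertainty = unname(ref[, "u"]),
    expanded_uncertainty = k * unname(ref[, "u"]),
    k = k,
    label = NA_character_
  )
}

empty_peaks <- function(k) {
  tibble(center = numeric(), height = numeric(), prominence = numeric(),
         standard_uncertainty = numeric(), expanded_uncertainty = numeric(),
         k = numeric(), label = character())
}

#' Label profile peaks by array geometry
#'
#' In profile coordinates (membrane midplane at 0, cytoplasm positive): the
#' most cytoplasmic peak is the CheA/CheW baseplate (`AW`); peaks within
#' `bilayer_halfwindow` of 0 are membrane leaflets and are merged into a
#' single `IM` entry at their midplane (the membrane coordinate of record),
#' with the leaflet standard uncertainties combined as for a two-point
#' mean; remaining peaks between IM and AW are labelled `L1`, `L2`, ... in
#' order from the baseplate towards the membrane.
#'
#' @param peaks a peak tibble from [detect_peaks()].
#' @param bilayer_halfwindow nm window around 0 within which peaks are
#'   taken as membrane leaflets.
#' @return The tibble with `label` filled; when a leaflet pair is merged
#'   the result has one row fewer than the input.
#' @export
label_peaks <- function(peaks, bilayer_halfwindow = 4) {
  if (nrow(peaks) == 0) return(peaks)
  peaks <- arrange(peaks, .data$center)
  leaf <- which(abs(peaks$center) <= bilayer_halfwindow)
  if (length(leaf) >= 2) {
    # the two peaks closest to the midplane are the bilayer leaflets
    leaf <- leaf[order(abs(peaks$center[leaf]))][1:2]
    merged <- tibble(
      center = mean(peaks$center[leaf]),
      height = mean(peaks$height[leaf]),
      prominence = max(peaks$prominence[leaf]),
      standard_uncertainty =
        sqrt(sum(peaks$standard_uncertainty[leaf]^2)) / 2,
      expanded_uncertainty = NA_real_,
      k = peaks$k[leaf[1]],
      label = "IM"
    )
    merged$expanded_uncertainty <- merged$k * merged$standard_uncertainty
    peaks <- bind_rows(peaks[-leaf, , drop = FALSE], merged) |>
      arrange(.data$center)
  }
  lab <- peaks$label
  im <- which.min(abs(peaks$center))
  aw <- which.max(peaks$center)
  lab[im] <- "IM"
  lab[aw] <- "AW"
  mids <- setdiff(seq_len(nrow(peaks)), c(im, aw))
  mids <- mids[peaks$center[mids] > peaks$center[im] &
                 peaks$center[mids] < peaks$center[aw]]
  if (length(mids)) {
    # L1 is nearest the baseplate
    mids <- mids[order(peaks$center[mids], decreasing = TRUE)]
    lab[mids] <- paste0("L", seq_along(mids))
  }
  peaks$label <- lab
  peaks
}

#' Measure inter-layer distances from labelled peaks
#'
#' Reports the absolute distance from a reference peak (by default the
#' CheA/CheW baseplate) to every other labelled peak, with expanded
#' uncertainty `k * sqrt(u_ref^2 + u_peak^2)` on the member standard
#' uncertainties.
#'
#' @param peaks a labelled peak tibble ([detect_peaks()] + [label_peaks()];
#'   unlabelled peaks are labelled automatically).
#' @param reference_label label of the reference peak (must occur exactly
#'   once).
#' @return A `layer_report`: list with `reference_peak` and a `distances`
#'   tibble (`label`, `distance_nm`, `expanded_uncertainty_nm`, `k`).
#' @export
measure_layers <- function(peaks, reference_label = "AW") {
  if (all(is.na(peaks$label))) peaks <- label_peaks(peaks)
  ref <- which(peaks$label == reference_label)
  if (length(ref) != 1L) {
    abort(sprintf("reference label '%s' must occur exactly once (found %d).",
                  reference_label, length(ref)))
  }
  k <- peaks$k[ref]
  u_ref <- peaks$standard_uncertainty[ref]
  others <- peaks[-ref, , drop = FALSE]
  others <- others[!is.na(others$label), , drop = FALSE]
  dist <- abs(others$center - peaks$center[ref])
  u <- sqrt(others$standard_uncertainty^2 + u_ref^2)
  report <- list(
    reference_peak = reference_label,
    distances = tibble(
      label = others$label,
      distance_nm = dist,
      expanded_uncertainty_nm = k * u,
      k = k
    ) |> arrange(.data$label)
  )
  structure(report, class = "layer_report")
}

#' @export
print.layer_report <- function(x, ...) {
  cat(sprintf("<layer_report> distances from %s peak\n", x$reference_peak))
  print(x$distances)
  invisible(x)
}

#' @method tidy layer_report
#' @export
tidy.layer_report <- function(x, ...) x$distances

#' @method glance layer_report
#' @export
glance.layer_report <- function(x, ...) {
  tibble(reference_peak = x$reference_peak,
         n_layers = nrow(x$distances),
         k = if (nrow(x$distances)) x$distances$k[1] else NA_real_)
}

#' Pool repeated distance measurements
#'
#' Combines measurements of the same quantity across tomograms or cells:
#' arithmetic mean with standard uncertainties propagated as
#' `sqrt(sum(u_i^2)) / n`, re-expanded by the common coverage factor.
#'
#' @param measurements data frame with columns `value`,
#'   `expanded_uncertainty` and `k` (all rows must share one `k`).
#' @param weighted if `TRUE`, use inverse-variance weighting instead of the
#'   arithmetic mean.
#' @return One-row tibble: `mean`, `expanded_uncertainty`, `k`, `n`.
#' @export
pool_measurements <- function(measurements, weighted = FALSE) {
  m <- as_tibble(measurements)
  if (nrow(m) < 1) abort("need at least one measurement.")
  if (length(unique(m$k)) != 1L) {
    abort("all measurements must share one coverage factor k.")
  }
  k <- m$k[1]
  u <- m$expanded_uncertainty / k
  if (weighted) {
    w <- 1 / u^2
    mean_v <- sum(w * m$value) / sum(w)
    u_pool <- sqrt(1 / sum(w))
  } else {
    mean_v <- mean(m$value)
    u_pool <- sqrt(sum(u^2)) / nrow(m)
  }
  tibble(mean = mean_v, expanded_uncertainty = k * u_pool, k = k, n = nrow(m))
}
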