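# AFM height maps: ingestion, line-wise tilt correction, and fibril
# height/area profiles in the same cross-section frame as the SMLM data.
# The pipeline consumes maps already converted to heights by the instrument
# software (contact-point fitting of force curves is out of scope); tip
# convolution is not deconvolved, a known systematic limit.

#' Construct an AFM height map
#'
#' @param heights Numeric matrix of heights in nm; rows are scan lines
#'   (x direction matches the SMLM frame rows).
#' @param pixel_size Pixel size in nm (default 39, a 20 um scan at
#'   512 px).
#' @param state Hydration state, `"dry"` or `"wet"`.
#' @param glass_mask Optional logical matrix marking background (glass)
#'   pixels.
#' @return An `afm_map`.
#' @export
afm_map <- function(heights, pixel_size = 39, state = c("wet", "dry"),
                    glass_mask = NULL) {
  state <- match.arg(state)
  if (pixel_size <= 0) abort("pixel_size must be > 0",
                             class = "rimap_input_error")
  if (!all(is.finite(heights))) abort("height grid must be finite",
                                      class = "rimap_input_error")
  structure(list(heights = heights, pixel_size = pixel_size, state = state,
                 glass_mask = glass_mask),
            class = "afm_map")
}

#' @export
print.afm_map <- function(x, ...) {
  cat("<afm_map>", nrow(x$heights), "x", ncol(x$heights), "px @",
      x$pixel_size, "nm,", x$state, "\n")
  invisible(x)
}

#' Read / write AFM maps
#'
#' Reads a 32-bit float TIFF (heights normalized to the stored maximum kept
#' in a `.json` sidecar) or a whitespace-delimited ASCII grid with a sidecar
#' header (`<path>.json` with fields `pixel_size`, `state`, and for TIFF
#' `scale_nm`).
#'
#' @param path File path (`.tif`/`.tiff` or ASCII grid).
#' @return An `afm_map`.
#' @export
read_afm_map <- function(path) {
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    scale <- meta$scale_nm %||% 1
    m <- m * scale
  } else {
    m <- as.matrix(read.table(path))
    dimnames(m) <- NULL
  }
  afm_map(m, pixel_size = meta$pixel_size %||% 39,
          state = meta$state %||% "wet")
}

#' @rdname read_afm_map
#' @param map An `afm_map`.
#' @export
write_afm_map <- function(map, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    scale <- max(abs(map$heights), 1e-12)
    tiff::writeTIFF(pmax(map$heights, 0) / scale, path, bits.per.sample = 32)
    jsonlite::write_json(list(pixel_size = map$pixel_size, state = map$state,
                              scale_nm = scale),
                         paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    write.table(map$heights, path, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(pixel_size = map$pixel_size,
                              state = map$state),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Line-wise tilt correction of an AFM map
#'
#' AFM scan lines carry independent offsets and tilts; for each line a
#' linear fit to the background (glass) pixels is subtracted, and the
#' background median of the corrected map is set to zero. Lines with fewer
#' than 3 background pixels get coefficients interpolated from neighboring
#' lines and are flagged.
#'
#' @param map An [afm_map()].
#' @param background_mask Logical matrix (same shape) marking glass pixels;
#'   defaults to the map's `glass_mask`.
#' @return The corrected `afm_map`; flagged line indices in attribute
#'   `interpolated_lines`.
#' @export
tilt_correct_lines <- function(map, background_mask = NULL) {
  mask <- background_mask %||% map$glass_mask
  if (is.null(mask)) abort("a background mask is required",
                           class = "rimap_input_error")
  h <- map$heights
  nl <- nrow(h); npx <- ncol(h)
  cols <- seq_len(npx)
  ab <- matrix(NA_real_, nl, 2)
  for (i in seq_len(nl)) {
    bg <- which(mask[i, ])
    if (length(bg) >= 3) {
      ft <- lm.fit(cbind(1, cols[bg]), h[i, bg])
      ab[i, ] <- ft$coefficients
    }
  }
  bad <- which(is.na(ab[, 1]))
  if (length(bad)) {
    good <- which(!is.na(ab[, 1]))
    if (!length(good)) abort("no scan line has background pixels",
                             class = "rimap_input_error")
    ab[bad, 1] <- approx(good, ab[good, 1], xout = bad, rule = 2)$y
    ab[bad, 2] <- approx(good, ab[good, 2], xout = bad, rule = 2)$y
  }
  corr <- h - (ab[, 1] + ab[, 2] %o% cols)
  corr <- corr - median(corr[mask])
  out <- afm_map(corr, pixel_size = map$pixel_size, state = map$state,
                 glass_mask = map$glass_mask)
  attr(out, "interpolated_lines") <- bad
  out
}

#' Fibril height and cross-sectional area from an AFM map
#'
#' Samples the (tilt-corrected) map into the fibril cross-section frame
#' defined by the SMLM axis and applies the identical sliding-window /
#' smoothed-maximum rule as the SMLM height estimator, then integrates the
#' cross-sectional area of the binned profile. Using the same estimator for
#' both modalities keeps their systematic biases matched.
#'
#' @param map An [afm_map()] (tilt-corrected, registered to the SMLM
#'   frame).
#' @param axis A [fit_fibril_axis()] result in the same coordinates.
#' @param window_npx Pixels per sliding window (the AFM analogue of
#'   `window_nlocs`).
#' @param max_X Lateral half-width (nm) of the band around the axis used
#'   for the profile.
#' @param s_margin Arclength margin (nm) trimmed from both curve ends,
#'   where the fitted axis is least constrained.
#' @param resample If `TRUE`, attach the half-sample resampling error.
#' @param n_resamples,seed Resampling controls.
#' @return List with `height` (a `height_estimate`), `area` (nm^2) and the
#'   cross-section `profile` tibble.
#' @export
afm_fibril_profile <- function(map, axis, window_npx = 40, max_X = 400,
                               s_margin = 300, resample = FALSE,
                               n_resamples = 1000, seed = 1) {
  h <- map$heights
  px <- map$pixel_size
  xi <- (seq_len(nrow(h)) - 1) * px
  yj <- (seq_len(ncol(h)) - 1) * px
  pts <- tibble(x_nm = rep(xi, times = ncol(h)),
                y_nm = rep(yj, each = nrow(h)),
                z_nm = as.vector(h))
  smax <- max(axis$dense$s_nm)
  # coarse prefilter around the axis to keep the projection cheap
  keep <- rep(FALSE, nrow(pts))
  sub <- axis$dense[seq(1, nrow(axis$dense), by = 10), ]
  for (k in seq_len(nrow(sub))) {
    keep <- keep | (abs(pts$x_nm - sub$x_nm[k]) < max_X + 150 &
                      abs(pts$y_nm - sub$y_nm[k]) < max_X + 150)
  }
  if (!any(keep)) abort("axis exits the AFM map bounds",
                        class = "rimap_input_error")
  cs <- transform_to_cross_section(pts[keep, ], axis)
  clipped <- mean(cs$boundary)
  cs <- cs[!cs$boundary & abs(cs$X_nm) <= max_X &
             cs$s_nm > s_margin & cs$s_nm < smax - s_margin, ]
  if (clipped > 0.5) warn("axis partially exits the AFM map; profile clipped")
  hc <- .height_core(cs$X_nm, cs$Z_nm, window_npx)
  sigma <- if (resample) {
    resample_height_error(cs, window_npx, n_resamples = n_resamples,
                          seed = seed)
  } else NA_real_
  height <- structure(list(H = hc$H, sigma_H = sigma, n_assumed = NA_real_,
                           window_nlocs = window_npx, profile = hc$profile),
                      class = "height_estimate")
  area <- cross_sectional_area(hc$profile)
  list(height = height, area = area, profile = hc$profile,
       cross_sections = cs)
}

#' AFM height along the fibril axis
#'
#' Per-arclength-window AFM crest heights (and resampling errors), for use
#' as the local ground truth of [map_ri_along_fibril()].
#'
#' @inheritParams afm_fibril_profile
#' @param s_centers Arclength window centers (nm).
#' @param half_window Half-width of each s window (nm).
#' @return Tibble `s_nm`, `H`, `sigma_H`.
#' @export
afm_height_along <- function(map, axis, s_centers, half_window = 250,
                             window_npx = 40, max_X = 400,
                             n_resamples = 200, seed = 1) {
  prof <- afm_fibril_profile(map, axis, window_npx = window_npx,
                             max_X = max_X)
  cs <- prof$cross_sections
  purrr::map_dfr(s_centers, function(s0) {
    sub <- cs[abs(cs$s_nm - s0) <= half_window, ]
    if (nrow(sub) < 2 * window_npx) {
      return(tibble(s_nm = s0, H = NA_real_, sigma_H = NA_real_))
    }
    hc <- .height_core(sub$X_nm, sub$Z_nm, window_npx)
    sig <- resample_height_error(sub, window_npx, n_resamples = n_resamples,
                                 seed = seed)
    tibble(s_nm = s0, H = hc$H, sigma_H = sig)
  })
}

#' Fibril axis from an AFM ridge
#'
#' Height-weighted centroid of the above-threshold pixels of each scan
#' line, fit with [fit_fibril_axis()]. The weighted centroid is sub-pixel
#' accurate, unlike medians of the thresholded pixel set, which are
#' quantized by the scan grid.
#'
#' @param map A (tilt-corrected) [afm_map()].
#' @param threshold Fraction of the map maximum defining the ridge
#'   (default 0.3).
#' @param ... Passed to [fit_fibril_axis()].
#' @return A `fibril_axis`.
#' @export
afm_ridge_axis <- function(map, threshold = 0.3, ...) {
  h <- map$heights
  thr <- threshold * max(h)
  px <- map$pixel_size
  pts <- purrr::map_dfr(seq_len(nrow(h)), function(i) {
    j <- which(h[i, ] > thr)
    if (length(j) < 2) return(NULL)
    w <- h[i, j]
    tibble(x_nm = (i - 1) * px,
           y_nm = (sum(w * (j - 1)) / sum(w)) * px)
  })
  if (nrow(pts) < 10) abort("no usable ridge found",
                            class = "rimap_input_error")
  fit_fibril_axis(pts, bin_nm = 0, ...)
}
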