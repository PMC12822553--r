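# End-to-end fibril analysis: stack -> localizations -> geometry ->
# refractive index. Mirrors the experimental workflow: prelocalize and fit
# with the no-layer model, track fiducials and correct drift, fix defocus
# and tilt on the glass-bound dyes, refit the fibril molecules per assumed
# refractive index with the layer model, and intersect the resulting
# height-vs-n line with the AFM height.

#' Extract fiducial tracks from a localization table
#'
#' Fiducial beads are bright and present in (nearly) every frame; they are
#' identified as positions where localizations recur in at least
#' `min_fraction` of all frames within `radius`.
#'
#' @param localizations Tibble with `frame`, `x_nm`, `y_nm` (uncorrected).
#' @param n_frames Total number of frames in the acquisition.
#' @param radius Clustering radius in nm (generous, to tolerate drift).
#' @param min_fraction Minimum fraction of frames a fiducial must appear in.
#' @return Tibble `fid_id`, `frame`, `x_nm`, `y_nm` suitable for
#'   [correct_drift()].
#' @export
extract_fiducial_tracks <- function(localizations, n_frames, radius = 400,
                                    min_fraction = 0.5) {
  locs <- localizations
  remaining <- rep(TRUE, nrow(locs))
  out <- list()
  fid <- 0L
  while (any(remaining)) {
    idx <- which(remaining)
    # densest remaining position: most neighbors within radius
    counts <- vapply(idx, function(i) {
      sum((locs$x_nm[idx] - locs$x_nm[i])^2 +
            (locs$y_nm[idx] - locs$y_nm[i])^2 <= radius^2)
    }, numeric(1))
    best <- idx[which.max(counts)]
    members <- idx[(locs$x_nm[idx] - locs$x_nm[best])^2 +
                     (locs$y_nm[idx] - locs$y_nm[best])^2 <= radius^2]
    if (length(unique(locs$frame[members])) < min_fraction * n_frames) break
    fid <- fid + 1L
    tr <- locs[members, c("frame", "x_nm", "y_nm")]
    tr <- dplyr::summarise(dplyr::group_by(tr, .data$frame),
                           x_nm = mean(.data$x_nm), y_nm = mean(.data$y_nm),
                           .groups = "drop")
    tr$fid_id <- fid
    out[[fid]] <- tr
    remaining[members] <- FALSE
  }
  if (!length(out)) {
    return(tibble(fid_id = integer(), frame = integer(),
                  x_nm = numeric(), y_nm = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Analyze one fibril end to end
#'
#' Runs the complete refractive-index pipeline on an image stack of a
#' single, pre-segmented fibril.
#'
#' @param stack List of count frames.
#' @param system An [optical_system()]; its `defocus` is the initial guess
#'   refined on the glass-bound dyes.
#' @param h_afm A `height_estimate` of the AFM fibril height (e.g. from
#'   [afm_fibril_profile()] with `resample = TRUE`).
#' @param fibril_region Predicate `function(x_nm, y_nm)` returning `TRUE`
#'   inside the fibril footprint (fibrils arrive pre-segmented).
#' @param axis Optional pre-fit [fit_fibril_axis()] result (e.g. from the
#'   registered AFM ridge, which is much denser than a sparse localization
#'   set); when `NULL` the axis is fit to the fibril localizations.
#' @param ri_grid Assumed refractive indices for the refits (default
#'   1.38-1.48 in steps of 0.02).
#' @param absolute_threshold,relative_threshold Prelocalization thresholds.
#' @param llr_max Localizations with `llr >= llr_max` are discarded.
#' @param window_nlocs Sliding-window size of the height estimator.
#' @param debris_offset Debris height (nm) added to SMLM heights.
#' @param dbscan_eps,dbscan_min_samples Outlier-filter parameters.
#' @param n_resamples,n_draws Error-estimation controls.
#' @param scan_range Defocus search range (nm).
#' @param seed RNG seed for the resampling steps.
#' @return A `fibril_analysis` list: the [estimate_refractive_index()]
#'   result (`ri`), per-n heights, the reference plane, axis, filtered
#'   cross-sections (reference n), and the localization table.
#' @export
analyze_fibril <- function(stack, system, h_afm, fibril_region,
                           axis = NULL,
                           ri_grid = seq(1.38, 1.48, by = 0.02),
                           absolute_threshold = 40, relative_threshold = 2,
                           llr_max = 600, window_nlocs = 40,
                           debris_offset = 0, dbscan_eps = 30,
                           dbscan_min_samples = 10, n_resamples = 1000,
                           n_draws = 10000, scan_range = c(300, 700),
                           seed = 1) {
  glass_sample <- layered_sample(system$n_ambient, 0)
  locs0 <- localize_stack(stack, system, glass_sample,
                          absolute_threshold = absolute_threshold,
                          relative_threshold = relative_threshold,
                          keep_rois = TRUE, z_range = c(-150, 400))
  rois <- attr(locs0, "rois")
  n_frames <- length(stack)
  fid_tracks <- extract_fiducial_tracks(locs0, n_frames)
  locs <- correct_drift(locs0, fid_tracks)
  # discard the fiducial localizations themselves
  is_fid <- rep(FALSE, nrow(locs))
  for (f in unique(fid_tracks$fid_id)) {
    tr <- fid_tracks[fid_tracks$fid_id == f, ]
    is_fid <- is_fid | (sqrt((locs$x_nm - mean(tr$x_nm))^2 +
                               (locs$y_nm - mean(tr$y_nm))^2) < 500)
  }
  ok_fit <- locs$converged & locs$llr < llr_max
  in_fib <- fibril_region(locs$x_nm, locs$y_nm)
  glass_idx <- which(!is_fid & ok_fit & !in_fib)
  fib_idx <- which(!is_fid & ok_fit & in_fib)
  if (length(glass_idx) < 10) {
    abort("too few glass-bound localizations for the reference plane",
          class = "rimap_input_error")
  }
  # fitting must use the raw (uncorrected) coordinates the pixels were
  # recorded at; the drift-corrected coordinates are for geometry only
  plane <- fit_reference_plane_and_defocus(
    rois[glass_idx], system, scan_range = scan_range,
    init_positions = locs0[glass_idx, c("x_nm", "y_nm")])
  sys <- system
  sys$defocus <- plane$fitted_defocus
  if (is.null(axis)) axis <- fit_fibril_axis(locs[fib_idx, ])
  # refit the fibril molecules per assumed refractive index (layer fixed at
  # the AFM height), lateral positions held from the reference fit
  fib_rois <- rois[fib_idx]
  init_pos <- tibble(x_nm = locs0$x_nm[fib_idx], y_nm = locs0$y_nm[fib_idx],
                     z_nm = h_afm$H)
  corrected_pos <- tibble(x_nm = locs$x_nm[fib_idx],
                          y_nm = locs$y_nm[fib_idx])
  heights <- list()
  cs_by_n <- list()
  ref_cs <- NULL
  for (n_assumed in ri_grid) {
    refit <- fit_rois(fib_rois, sys, layered_sample(n_assumed, h_afm$H),
                      fix_xy = TRUE, init_positions = init_pos,
                      z_range = c(0, max(400, h_afm$H + 200)))
    refit$x_nm <- corrected_pos$x_nm
    refit$y_nm <- corrected_pos$y_nm
    refit$loc_id <- seq_len(nrow(refit))
    refit <- apply_reference_plane(refit, plane)
    keep <- refit$llr < llr_max
    cs <- transform_to_cross_section(refit[keep, ], axis)
    cs <- filter_outliers(cs, eps = dbscan_eps,
                          min_samples = dbscan_min_samples)
    h <- estimate_height(cs, window_nlocs = window_nlocs,
                         debris_offset = debris_offset,
                         n_assumed = n_assumed, resample = TRUE,
                         n_resamples = n_resamples, seed = seed)
    heights[[as.character(n_assumed)]] <- h
    cs_by_n[[as.character(n_assumed)]] <- cs
    if (is.null(ref_cs)) ref_cs <- cs
  }
  gl <- plane$glass_localizations
  sigma_ref <- sd(gl$z_nm) / sqrt(nrow(gl))
  ri <- estimate_refractive_index(heights, h_afm, n_draws = n_draws,
                                  seed = seed, sigma_common = sigma_ref)
  structure(list(ri = ri, heights = heights, plane = plane, axis = axis,
                 sigma_ref = sigma_ref,
                 cross_sections = ref_cs, cross_sections_by_n = cs_by_n,
                 localizations = locs, fiducial_tracks = fid_tracks,
                 glass_index = glass_idx, fibril_index = fib_idx),
            class = "fibril_analysis")
}

#' @export
print.fibril_analysis <- function(x, ...) {
  cat("<fibril_analysis>\n  ")
  print(x$ri)
  cat("  defocus", round(x$plane$fitted_defocus, 1), "nm, ",
      length(x$fibril_index), "fibril /", length(x$glass_index),
      "glass localizations\n")
  invisible(x)
}

#' Fibril footprint predicate from an AFM map
#'
#' Marks lab-frame positions whose nearest AFM pixel exceeds a height
#' threshold — a pre-registered segmentation of the fibril region.
#'
#' @param map A tilt-corrected [afm_map()] registered to the SMLM frame.
#' @param threshold Height threshold in nm (default 25% of the map
#'   maximum).
#' @param dilate_nm Margin added around the footprint, nm.
#' @return `function(x_nm, y_nm) -> logical`.
#' @export
afm_region_predicate <- function(map, threshold = NULL, dilate_nm = 200) {
  h <- map$heights
  if (is.null(threshold)) threshold <- 0.25 * max(h)
  px <- map$pixel_size
  pad <- ceiling(dilate_nm / px)
  mask <- h > threshold
  if (pad > 0) {
    m2 <- mask
    for (di in -pad:pad) for (dj in -pad:pad) {
      si <- seq_len(nrow(mask)) + di
      sj <- seq_len(ncol(mask)) + dj
      ok_i <- si >= 1 & si <= nrow(mask)
      ok_j <- sj >= 1 & sj <= ncol(mask)
      m2[which(ok_i), which(ok_j)] <-
        m2[which(ok_i), which(ok_j)] | mask[si[ok_i], sj[ok_j]]
    }
    mask <- m2
  }
  function(x_nm, y_nm) {
    i <- pmin(pmax(round(x_nm / px) + 1, 1), nrow(mask))
    j <- pmin(pmax(round(y_nm / px) + 1, 1), ncol(mask))
    mask[cbind(i, j)]
  }
}

#' Run one fully synthetic end-to-end experiment
#'
#' Generates a surface-labeled fibril phantom, renders a blinking stack and
#' AFM maps, and runs the complete analysis pipeline against them. The AFM
#' sliding window is chosen to span the same lateral extent as the SMLM
#' windows, so the crest biases of the two height estimators match.
#'
#' @param seed Master seed; all random streams derive from it.
#' @param n_true True fibril refractive index.
#' @param radius_wet,radius_dry Fibril radii, nm.
#' @param frames Number of rendered frames.
#' @param mean_photons Mean photons per burst.
#' @param ri_grid Assumed refractive indices for the refits.
#' @param window_nlocs SMLM height-window size.
#' @param n_resamples,n_draws Error-estimation controls.
#' @param label_density,glass_density Label densities, um^-2.
#' @param fibril_length Fibril length, nm.
#' @return List: `analysis` (a `fibril_analysis`), `ri` (the final
#'   matched-window `ri_estimate`), `h_afm`, `swelling`, `truth` inputs.
#' @export
run_synthetic_experiment <- function(seed = 1, n_true = 1.43,
                                     radius_wet = 100, radius_dry = 60,
                                     frames = 450, mean_photons = 3000,
                                     ri_grid = c(1.38, 1.43, 1.48),
                                     window_nlocs = 40,
                                     n_resamples = 200, n_draws = 5000,
                                     label_density = 350,
                                     glass_density = 3,
                                     fibril_length = 5000) {
  phantom <- fibril_phantom(length = fibril_length, radius_wet = radius_wet,
                            radius_dry = radius_dry, n_true = n_true,
                            label_density = label_density,
                            glass_density = glass_density,
                            field_nm = c(10240, 10240))
  system <- optical_system(oversampling = 2)
  emitters <- generate_phantom(phantom, seed = seed)
  acq <- acquisition_model(frames = frames, frame_px = c(64, 64),
                           p_on = 0.0013, mean_photons = mean_photons,
                           background = 10, seed = seed + 1000L)
  ren <- suppressWarnings(render_smlm_stack(emitters, acq, system, phantom))
  afm_wet <- render_afm_map(phantom, noise_sigma = 1, state = "wet",
                            seed = seed + 2000L)
  afm_dry <- render_afm_map(phantom, noise_sigma = 1, state = "dry",
                            seed = seed + 3000L)
  axis_afm <- afm_ridge_axis(afm_wet)
  prof_wet <- afm_fibril_profile(afm_wet, axis_afm, resample = TRUE,
                                 n_resamples = n_resamples,
                                 seed = seed + 4000L)
  ana <- analyze_fibril(ren$stack, system, prof_wet$height,
                        fibril_region = afm_region_predicate(afm_wet),
                        axis = axis_afm,
                        ri_grid = ri_grid,
                        absolute_threshold = 16, relative_threshold = 1.4,
                        window_nlocs = window_nlocs,
                        n_resamples = n_resamples, n_draws = n_draws,
                        seed = seed + 5000L)
  # AFM window matched to the effective lateral extent of the SMLM
  # windows: the SMLM window width in observed X, widened by the lateral
  # localization noise (a window of width W in observed X aggregates true
  # positions with variance W^2/12 + sigma_lat^2), expressed in AFM pixels
  cs <- ana$cross_sections
  locs_fib <- ana$localizations[ana$fibril_index, ]
  med_N <- stats::median(locs_fib$photons)
  med_B <- stats::median(locs_fib$background)
  sys_fit <- system
  sys_fit$defocus <- ana$plane$fitted_defocus
  fi_x <- rimap_fisher_lateral(sys_fit,
                               layered_sample(ri_grid[ceiling(
                                 length(ri_grid) / 2)], prof_wet$height$H),
                               emitter_state(axial_position =
                                               prof_wet$height$H,
                                             signal_photons = med_N,
                                             background_per_pixel = med_B))
  sigma_lat <- 1 / sqrt(fi_x)
  dens_smlm <- nrow(cs) / diff(range(cs$X_nm))
  W_obs <- window_nlocs / dens_smlm
  W_eff <- sqrt(W_obs^2 + 12 * sigma_lat^2)
  cs_afm <- prof_wet$cross_sections
  dens_afm <- nrow(cs_afm) / diff(range(cs_afm$X_nm))
  w_afm <- max(10, round(W_eff * dens_afm))
  prof_matched <- afm_fibril_profile(afm_wet, axis_afm, window_npx = w_afm,
                                     resample = TRUE,
                                     n_resamples = n_resamples,
                                     seed = seed + 6000L)
  ri <- estimate_refractive_index(ana$heights, prof_matched$height,
                                  n_draws = n_draws, seed = seed + 7000L,
                                  sigma_common = ana$sigma_ref)
  # cross-sectional areas are AFM-only: integrate both states with the
  # same fixed window (~40 nm lateral extent on the 39 nm grid), which the
  # profile integral tolerates far better than the blur-matched crest
  # window
  prof_area_wet <- afm_fibril_profile(afm_wet, axis_afm, window_npx = 120)
  prof_area_dry <- afm_fibril_profile(afm_dry, axis_afm, window_npx = 120)
  swelling <- swelling_and_dry_index(prof_area_dry$area,
                                     prof_area_wet$area, ri$n)
  list(analysis = ana, ri = ri, h_afm = prof_matched$height,
       swelling = swelling, phantom = phantom, system = system,
       emitters = emitters, rendered = ren,
       afm = list(wet = afm_wet, dry = afm_dry, window_npx = w_afm))
}
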