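# Fibril analysis: from drift-corrected localizations plus AFM heights to
# refractive-index estimates, along-axis maps and error decomposition.

#' Correct lateral drift using fiducial markers
#'
#' Subtracts the mean fiducial displacement, interpolated per frame, from
#' every localization. With several fiducials their centered trajectories
#' are averaged.
#'
#' @param localizations Tibble with `frame`, `x_nm`, `y_nm`.
#' @param fiducial_tracks Tibble with `frame`, `x_nm`, `y_nm` and optionally
#'   `fid_id` (one track per fiducial).
#' @return The corrected localizations; the fiducial residual RMS (nm) is
#'   attached as attribute `residual_rms`.
#' @export
correct_drift <- function(localizations, fiducial_tracks) {
  ft <- fiducial_tracks
  if (is.null(ft) || nrow(ft) == 0) {
    abort("no fiducial tracks supplied", class = "rimap_input_error")
  }
  if (!"fid_id" %in% names(ft)) ft$fid_id <- 1L
  fr_range <- range(ft$frame)
  missing <- localizations$frame[localizations$frame < fr_range[1] |
                                   localizations$frame > fr_range[2]]
  if (length(missing)) {
    abort(sprintf(
      "no fiducial covers frames %g..%g (fiducials span %g..%g)",
      min(missing), max(missing), fr_range[1], fr_range[2]),
      class = "rimap_input_error")
  }
  centered <- dplyr::mutate(dplyr::group_by(ft, .data$fid_id),
                            dx = .data$x_nm - mean(.data$x_nm),
                            dy = .data$y_nm - mean(.data$y_nm))
  drift <- dplyr::summarise(dplyr::group_by(centered, .data$frame),
                            dx = mean(.data$dx), dy = mean(.data$dy),
                            .groups = "drop")
  # anchor the correction at the first frame so positions stay referenced
  # to the start of the acquisition
  drift$dx <- drift$dx - drift$dx[which.min(drift$frame)]
  drift$dy <- drift$dy - drift$dy[which.min(drift$frame)]
  dx <- approx(drift$frame, drift$dx, xout = localizations$frame,
               rule = 2)$y
  dy <- approx(drift$frame, drift$dy, xout = localizations$frame,
               rule = 2)$y
  out <- localizations
  out$x_nm <- out$x_nm - dx
  out$y_nm <- out$y_nm - dy
  resid <- dplyr::mutate(
    centered,
    rx = .data$dx - approx(drift$frame, drift$dx, xout = .data$frame,
                           rule = 2)$y,
    ry = .data$dy - approx(drift$frame, drift$dy, xout = .data$frame,
                           rule = 2)$y)
  attr(out, "residual_rms") <- sqrt(mean(resid$rx^2 + resid$ry^2))
  out
}

#' Fit the reference plane and the acquisition defocus
#'
#' Uses fluorophores bound directly to the coverslip, adjacent to the
#' fibrils: the defocus is the value at which the refit glass localizations
#' have mean z = 0, and the residual tilt plane through their (x, y, z) is
#' the reference plane. Apply the result to all localizations with
#' [apply_reference_plane()].
#'
#' @param glass_rois List of `molecule_roi` objects of glass-bound molecules.
#' @param system An [optical_system()]; its `defocus` is the initial guess.
#' @param scan_range Defocus search interval in nm.
#' @param tol Convergence tolerance on the mean glass z (nm).
#' @param init_positions Optional tibble of lateral positions (`x_nm`,
#'   `y_nm`) from an earlier fit; when given, the defocus scan refits only
#'   the axial positions, which is considerably faster.
#' @return A `reference_plane`: intercept and slopes of the tilt plane (nm,
#'   nm/nm), `fitted_defocus` (nm), and the final glass localizations.
#' @export
fit_reference_plane_and_defocus <- function(glass_rois, system,
                                            scan_range = c(300, 700),
                                            tol = 0.5,
                                            init_positions = NULL) {
  if (length(glass_rois) < 10) {
    abort("need >= 10 glass-bound localizations", class = "rimap_input_error")
  }
  glass_sample <- layered_sample(n_layer = system$n_ambient, thickness = 0)
  mean_z <- function(d) {
    sys <- system
    sys$defocus <- d
    locs <- fit_rois(glass_rois, sys, glass_sample, z_range = c(-150, 400),
                     fix_xy = !is.null(init_positions),
                     init_positions = init_positions)
    if (!is.null(init_positions)) {
      locs$x_nm <- init_positions$x_nm
      locs$y_nm <- init_positions$y_nm
    }
    list(m = mean(locs$z_nm), locs = locs)
  }
  d0 <- min(max(system$defocus, scan_range[1]), scan_range[2])
  e0 <- mean_z(d0)
  d1 <- d0 + if (e0$m > 0) 25 else -25
  e1 <- mean_z(d1)
  trace <- tibble(defocus = c(d0, d1), mean_z = c(e0$m, e1$m))
  for (it in 1:8) {
    if (abs(e1$m) < tol) break
    if (e1$m == e0$m) break
    d2 <- d1 - e1$m * (d1 - d0) / (e1$m - e0$m)
    if (d2 < scan_range[1] || d2 > scan_range[2]) {
      abort(sprintf(
        "defocus scan range [%g, %g] exhausted without a zero crossing",
        scan_range[1], scan_range[2]),
        class = "rimap_optim_error", body = list(trace = trace))
    }
    d0 <- d1; e0 <- e1
    d1 <- d2; e1 <- mean_z(d2)
    trace <- dplyr::bind_rows(trace, tibble(defocus = d1, mean_z = e1$m))
  }
  locs <- e1$locs
  fit <- lm(z_nm ~ x_nm + y_nm, data = locs)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope_x = unname(coef(fit)[2]),
                 slope_y = unname(coef(fit)[3]),
                 fitted_defocus = d1,
                 glass_localizations = locs,
                 trace = trace),
            class = "reference_plane")
}

#' @export
print.reference_plane <- function(x, ...) {
  cat("<reference_plane> defocus", round(x$fitted_defocus, 1),
      "nm  tilt", signif(x$slope_x, 3), "/", signif(x$slope_y, 3),
      " offset", round(x$intercept, 2), "nm\n")
  invisible(x)
}

#' @rdname fit_reference_plane_and_defocus
#' @param localizations Tibble with `x_nm`, `y_nm`, `z_nm`.
#' @param plane A `reference_plane`.
#' @export
apply_reference_plane <- function(localizations, plane) {
  out <- localizations
  out$z_nm <- out$z_nm - (plane$intercept + plane$slope_x * out$x_nm +
                            plane$slope_y * out$y_nm)
  out
}

# ---------------------------------------------------------------------------

#' Fit the fibril central axis
#'
#' Least-squares planar spline (z = 0) through the lateral point cloud of a
#' single, pre-segmented fibril. The cloud is rotated onto its principal
#' axis and the lateral coordinate is fit as a B-spline of the longitudinal
#' one.
#'
#' @param localizations Tibble with `x_nm`, `y_nm`.
#' @param spline_order Spline order k (polynomial degree k - 1); the default
#'   4 is a cubic spline.
#' @param df Degrees of freedom of the B-spline basis (controls
#'   flexibility); default scales with fibril length (one knot per ~5 um,
#'   at least the polynomial degree + 1).
#' @param ds Arclength presampling step (nm) of the fitted curve.
#' @param bin_nm Longitudinal bin width (nm) for the robust pre-binning:
#'   the spline is fit through per-bin medians of the lateral coordinate
#'   (count-weighted), which suppresses the leverage of label clumps on the
#'   fibril flanks. Set to 0 to fit all points directly.
#' @return A `fibril_axis`: rotation, spline fit and a dense arclength
#'   parameterization usable by [transform_to_cross_section()].
#' @export
fit_fibril_axis <- function(localizations, spline_order = 4, df = NULL,
                            ds = 10, bin_nm = 250) {
  pts <- cbind(localizations$x_nm, localizations$y_nm)
  if (nrow(pts) < 10) abort("too few localizations for an axis fit",
                            class = "rimap_input_error")
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)
  rot <- ev$vectors            # columns: principal directions
  if (rot[1, 1] < 0) rot[, 1] <- -rot[, 1]   # deterministic orientation
  rot[, 2] <- c(-rot[2, 1], rot[1, 1])
  uv <- sweep(pts, 2, ctr) %*% rot
  span <- diff(range(uv[, 1]))
  if (span < 200 || span < 4 * diff(range(uv[, 2]))) {
    abort("degenerate (nearly point-like or isotropic) cloud",
          class = "rimap_input_error")
  }
  degree <- spline_order - 1
  if (is.null(df)) df <- max(degree + 1, ceiling(span / 5000) + degree)
  u <- uv[, 1]; v <- uv[, 2]
  bknots <- range(u)
  w <- rep(1, length(u))
  if (bin_nm > 0 && length(u) > 4 * (df + 1)) {
    bins <- floor((u - min(u)) / bin_nm)
    ub <- tapply(u, bins, median)
    vb <- tapply(v, bins, median)
    nb <- tapply(v, bins, length)
    if (length(ub) > df + 1) {
      u <- as.numeric(ub); v <- as.numeric(vb); w <- as.numeric(nb)
    }
  }
  fit <- lm(v ~ splines::bs(u, df = df, degree = degree,
                            Boundary.knots = bknots), weights = w)
  ugrid <- seq(bknots[1], bknots[2], by = ds)
  if (tail(ugrid, 1) < bknots[2]) ugrid <- c(ugrid, bknots[2])
  vgrid <- predict(fit, newdata = data.frame(u = ugrid))
  xy <- cbind(ugrid, vgrid) %*% t(rot)
  xy <- sweep(xy, 2, ctr, "+")
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  structure(list(center = ctr, rot = rot, fit = fit,
                 u_range = range(u), spline_order = spline_order, df = df,
                 dense = tibble(s_nm = s, x_nm = xy[, 1], y_nm = xy[, 2])),
            class = "fibril_axis")
}

#' @export
print.fibril_axis <- function(x, ...) {
  cat("<fibril_axis> length", round(max(x$dense$s_nm)), "nm, order",
      x$spline_order, ", df", x$df, "\n")
  invisible(x)
}

#' Transform localizations to fibril-centric cross-section coordinates
#'
#' Maps each localization to `(s, X, Z)` — arclength along the axis, signed
#' lateral offset (positive to the left of the tangent), and height — by
#' nearest-point projection onto the fitted axis. Points beyond the axis
#' endpoints are assigned to the endpoint and flagged.
#'
#' @param localizations Tibble with `x_nm`, `y_nm`, `z_nm` (extra columns
#'   are carried through).
#' @param axis A [fit_fibril_axis()] result.
#' @return The input tibble with added columns `s_nm`, `X_nm`, `Z_nm`,
#'   `boundary`.
#' @export
transform_to_cross_section <- function(localizations, axis) {
  dn <- axis$dense
  px <- localizations$x_nm
  py <- localizations$y_nm
  nv <- nrow(dn)
  # nearest dense vertex (chunked to bound memory)
  nearest <- integer(length(px))
  chunk <- max(1, floor(4e6 / nv))
  for (start in seq(1, length(px), by = chunk)) {
    idx <- start:min(start + chunk - 1, length(px))
    d2 <- outer(px[idx], dn$x_nm, "-")^2 + outer(py[idx], dn$y_nm, "-")^2
    nearest[idx] <- max.col(-d2, ties.method = "first")
  }
  s_out <- numeric(length(px))
  X_out <- numeric(length(px))
  bnd <- logical(length(px))
  for (k in seq_along(px)) {
    i <- nearest[k]
    # project onto the segment(s) adjacent to the nearest vertex;
    # equidistant ties resolve toward smaller s by evaluation order
    best <- NULL
    for (i0 in unique(pmax(pmin(c(i - 1, i), nv - 1), 1))) {
      ax <- dn$x_nm[i0]; ay <- dn$y_nm[i0]
      bx <- dn$x_nm[i0 + 1]; by <- dn$y_nm[i0 + 1]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      t <- ((px[k] - ax) * vx + (py[k] - ay) * vy) / L2
      tc <- min(max(t, 0), 1)
      qx <- ax + tc * vx; qy <- ay + tc * vy
      d2 <- (px[k] - qx)^2 + (py[k] - qy)^2
      if (is.null(best) || d2 < best$d2 - 1e-9) {
        cross <- vx * (py[k] - qy) - vy * (px[k] - qx)
        best <- list(d2 = d2,
                     s = dn$s_nm[i0] + tc * sqrt(L2),
                     X = sign(cross) * sqrt(d2),
                     clip = (i0 == 1 && t < 0) || (i0 == nv - 1 && t > 1))
      }
    }
    s_out[k] <- best$s
    X_out[k] <- best$X
    bnd[k] <- best$clip
  }
  out <- localizations
  out$s_nm <- s_out
  out$X_nm <- X_out
  out$Z_nm <- localizations$z_nm
  out$boundary <- bnd
  out
}

#' @rdname transform_to_cross_section
#' @param s_nm,X_nm Cross-section coordinates to map back to the lab frame.
#' @return For `cross_section_to_lab()`: tibble with `x_nm`, `y_nm`.
#' @export
cross_section_to_lab <- function(axis, s_nm, X_nm) {
  dn <- axis$dense
  x0 <- approx(dn$s_nm, dn$x_nm, xout = s_nm, rule = 2)$y
  y0 <- approx(dn$s_nm, dn$y_nm, xout = s_nm, rule = 2)$y
  # tangent from neighboring dense samples
  eps <- min(25, max(dn$s_nm) / 4)
  tx <- approx(dn$s_nm, dn$x_nm, xout = pmin(s_nm + eps, max(dn$s_nm)),
               rule = 2)$y -
    approx(dn$s_nm, dn$x_nm, xout = pmax(s_nm - eps, 0), rule = 2)$y
  ty <- approx(dn$s_nm, dn$y_nm, xout = pmin(s_nm + eps, max(dn$s_nm)),
               rule = 2)$y -
    approx(dn$s_nm, dn$y_nm, xout = pmax(s_nm - eps, 0), rule = 2)$y
  L <- sqrt(tx^2 + ty^2)
  tibble(x_nm = x0 + X_nm * (-ty / L), y_nm = y0 + X_nm * (tx / L))
}

# ---------------------------------------------------------------------------

# Exact DBSCAN (chunked neighbor search); min_samples counts the point
# itself, matching the scikit-learn definition the field uses.
.dbscan <- function(xy, eps, min_samples) {
  n <- nrow(xy)
  chunk <- max(1, floor(4e6 / n))
  nbrs <- vector("list", n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    d2 <- outer(xy[idx, 1], xy[, 1], "-")^2 + outer(xy[idx, 2], xy[, 2], "-")^2
    within <- d2 <= eps^2
    for (r in seq_along(idx)) nbrs[[idx[r]]] <- which(within[r, ])
  }
  core <- lengths(nbrs) >= min_samples
  label <- integer(n)          # 0 = unvisited/noise
  cl <- 0L
  for (i in which(core)) {
    if (label[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    label[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (k in nbrs[[j]]) {
        if (label[k] == 0L) {
          label[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  label
}

#' Remove outlier localizations by density clustering
#'
#' Density-based clustering (DBSCAN) in the cross-section `(X, Z)` plane;
#' only the main (largest) cluster is kept, removing unspecifically bound
#' dyes and mislocalizations.
#'
#' @param cross_sections Tibble with `X_nm`, `Z_nm`.
#' @param eps Neighborhood radius in nm.
#' @param min_samples Minimum neighbors (including the point) for a core
#'   point.
#' @return The filtered tibble; the removed fraction is attached as
#'   attribute `removed_fraction`.
#' @export
filter_outliers <- function(cross_sections, eps = 30, min_samples = 10) {
  lab <- .dbscan(cbind(cross_sections$X_nm, cross_sections$Z_nm),
                 eps, min_samples)
  if (all(lab == 0L)) {
    abort("all localizations classified as noise; revise eps / min_samples",
          class = "rimap_input_error")
  }
  main <- which.max(tabulate(lab))
  out <- cross_sections[lab == main, ]
  attr(out, "removed_fraction") <- 1 - nrow(out) / nrow(cross_sections)
  out
}

# ---------------------------------------------------------------------------

# Sliding-window crest height: windows of fixed localization count ordered
# by X, per-window median Z, 3-window centered moving average, maximum.
.height_core <- function(X, Z, window_nlocs, step = NULL,
                         smooth_windows = 3) {
  n <- length(X)
  w <- min(window_nlocs, n)
  if (is.null(step)) step <- max(1L, round(w / 10))
  o <- order(X)
  Xs <- X[o]; Zs <- Z[o]
  starts <- seq(1L, n - w + 1L, by = step)
  if (tail(starts, 1) != n - w + 1L) starts <- c(starts, n - w + 1L)
  med <- vapply(starts, function(i) median(Zs[i:(i + w - 1L)]), numeric(1))
  pos <- vapply(starts, function(i) median(Xs[i:(i + w - 1L)]), numeric(1))
  if (smooth_windows > 1 && length(med) >= smooth_windows) {
    hw <- (smooth_windows - 1) %/% 2
    sm <- vapply(seq_along(med), function(i) {
      mean(med[max(1, i - hw):min(length(med), i + hw)])
    }, numeric(1))
  } else sm <- med
  list(H = max(sm), profile = tibble(X_nm = pos, Z_med = med, Z_smooth = sm))
}

#' Estimate the fibril height from a cross-section
#'
#' Orders the (filtered) localizations by lateral offset X, computes the
#' median height Z within sliding windows of a fixed localization count,
#' smooths the resulting profile with a centered moving average, and takes
#' the maximum as the fibril crest height. The median AFM height of debris
#' at the coverslip (which offsets the SMLM reference plane) is added.
#'
#' @param cross_sections Tibble with `X_nm`, `Z_nm` (already
#'   outlier-filtered).
#' @param window_nlocs Localizations per sliding window (>= 10).
#' @param debris_offset Debris height added to the SMLM height, nm.
#' @param n_assumed Refractive index assumed when fitting these
#'   localizations (recorded in the result).
#' @param smooth_windows Width (in windows) of the moving average.
#' @param resample If `TRUE`, attach the half-sample resampling error
#'   ([resample_height_error()]) as `sigma_H`.
#' @param n_resamples,seed Resampling controls.
#' @return A `height_estimate`: `H`, `sigma_H`, `n_assumed`, `window_nlocs`
#'   and the height profile.
#' @export
estimate_height <- function(cross_sections, window_nlocs = 40,
                            debris_offset = 0, n_assumed = NA_real_,
                            smooth_windows = 3, resample = FALSE,
                            n_resamples = 1000, seed = 1) {
  if (window_nlocs < 10) abort("window_nlocs must be >= 10",
                               class = "rimap_input_error")
  if (nrow(cross_sections) < window_nlocs) {
    abort("fewer localizations than one window", class = "rimap_input_error")
  }
  hc <- .height_core(cross_sections$X_nm, cross_sections$Z_nm, window_nlocs,
                     smooth_windows = smooth_windows)
  sigma <- if (resample) {
    resample_height_error(cross_sections, window_nlocs,
                          n_resamples = n_resamples, seed = seed,
                          smooth_windows = smooth_windows)
  } else NA_real_
  structure(list(H = hc$H + debris_offset, sigma_H = sigma,
                 n_assumed = n_assumed, window_nlocs = window_nlocs,
                 profile = hc$profile),
            class = "height_estimate")
}

#' @export
print.height_estimate <- function(x, ...) {
  cat("<height_estimate> H =", round(x$H, 2), "nm",
      if (!is.na(x$sigma_H)) paste0("+/- ", signif(x$sigma_H, 3), " nm"),
      if (!is.na(x$n_assumed)) paste0(" (n assumed ", x$n_assumed, ")"),
      "\n")
  invisible(x)
}

#' Height error by half-sample resampling
#'
#' Randomly selects half the localizations of a cross-section (without
#' replacement), recomputes the sliding-window height, repeats
#' `n_resamples` times, and returns the standard deviation of the resulting
#' distribution divided by sqrt(2) — the standard error of the full-sample
#' height estimate.
#'
#' @inheritParams estimate_height
#' @param n_resamples Number of half-sample draws.
#' @param seed RNG seed.
#' @return Height standard error in nm.
#' @export
resample_height_error <- function(cross_sections, window_nlocs = 40,
                                  n_resamples = 1000, seed = 1,
                                  smooth_windows = 3) {
  X <- cross_sections$X_nm
  Z <- cross_sections$Z_nm
  n <- length(X)
  half <- floor(n / 2)
  if (half < window_nlocs) {
    abort("need at least 2 x window_nlocs localizations",
          class = "rimap_input_error")
  }
  hs <- withr_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      idx <- sample.int(n, half)
      .height_core(X[idx], Z[idx], window_nlocs,
                   smooth_windows = smooth_windows)$H
    }, numeric(1))
  })
  sd(hs) / sqrt(2)
}

# evaluate expr with a local RNG seed, restoring the global state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# ---------------------------------------------------------------------------

#' Refractive index from the SMLM/AFM height intersection
#'
#' The apparent SMLM height of a fibril grows with the refractive index
#' assumed in the psf model. A line is fit through the `(n_assumed, H_SMLM)`
#' pairs and intersected with the AFM ground-truth height; the crossing
#' point is the fibril's refractive index.
#'
#' @param heights Tibble with columns `n_assumed`, `H` and optionally
#'   `sigma_H` (nm), or a list of `height_estimate` objects.
#' @param h_afm A `height_estimate` for the AFM height (or
#'   `list(H =, sigma_H =)`).
#' @param n_draws,seed Monte Carlo controls for [propagate_ri_error()].
#' @param sigma_common Common-mode height error (nm) shared by all SMLM grid
#'   points — e.g. the standard error of the reference plane the heights are
#'   measured against; it shifts the whole line rather than averaging out.
#' @return An `ri_estimate`: `n`, `sigma_n`, fit `slope` (nm per refractive
#'   index unit) and `intercept` (nm), plus a flag when the intersection
#'   falls outside [1.30, 1.60].
#' @export
estimate_refractive_index <- function(heights, h_afm, n_draws = 10000,
                                      seed = 1, sigma_common = 0) {
  if (is.list(heights) && inherits(heights[[1]], "height_estimate")) {
    heights <- purrr::map_dfr(heights, function(h)
      tibble(n_assumed = h$n_assumed, H = h$H, sigma_H = h$sigma_H))
  }
  if (nrow(heights) < 3) abort("need >= 3 refractive-index grid points",
                               class = "rimap_input_error")
  fit <- lm(H ~ n_assumed, data = heights)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope <= 0) {
    abort("non-positive slope of H_SMLM vs assumed n; violates the model",
          class = "rimap_model_error")
  }
  n_hat <- (h_afm$H - intercept) / slope
  has_sigma <- "sigma_H" %in% names(heights) && !anyNA(heights$sigma_H) &&
    !is.null(h_afm$sigma_H) && !is.na(h_afm$sigma_H)
  sigma_n <- if (has_sigma) {
    propagate_ri_error(heights, h_afm, n_draws = n_draws, seed = seed,
                       sigma_common = sigma_common)
  } else NA_real_
  outside <- n_hat < 1.30 || n_hat > 1.60
  if (outside) {
    warn(sprintf("refractive-index intersection %.3f outside [1.30, 1.60]",
                 n_hat))
  }
  structure(list(n = n_hat, sigma_n = sigma_n, slope = slope,
                 intercept = intercept, heights = heights,
                 h_afm = list(H = h_afm$H, sigma_H = h_afm$sigma_H),
                 outside_range = outside),
            class = "ri_estimate")
}

#' @export
print.ri_estimate <- function(x, ...) {
  cat("<ri_estimate> n =", round(x$n, 4),
      if (!is.na(x$sigma_n)) paste0("+/- ", signif(x$sigma_n, 3)),
      " (slope ", round(x$slope, 1), " nm per RI unit)\n")
  invisible(x)
}

#' Monte Carlo propagation of height errors into the refractive index
#'
#' Draws perturbed heights from the Gaussian error distributions of every
#' SMLM grid point and of the AFM height, recomputes the line fit and its
#' intersection for each draw, and returns the standard deviation of the
#' refractive-index estimates.
#'
#' @inheritParams estimate_refractive_index
#' @param n_draws Number of Monte Carlo draws.
#' @param sigma_common Common-mode (reference-plane) height error, nm.
#' @return Standard deviation of the refractive-index estimate.
#' @export
propagate_ri_error <- function(heights, h_afm, n_draws = 10000, seed = 1,
                               sigma_common = 0) {
  x <- heights$n_assumed
  m <- length(x)
  xc <- x - mean(x)
  Sxx <- sum(xc^2)
  withr_seed(seed, {
    pert <- matrix(rnorm(n_draws * m, mean = rep(heights$H, each = n_draws),
                         sd = rep(heights$sigma_H, each = n_draws)),
                   n_draws, m)
    if (sigma_common > 0) pert <- pert + rnorm(n_draws, 0, sigma_common)
    ybar <- rowMeans(pert)
    slope_d <- (pert %*% xc) / Sxx
    inter_d <- ybar - slope_d * mean(x)
    afm_d <- rnorm(n_draws, h_afm$H, h_afm$sigma_H)
    sd((afm_d - inter_d) / slope_d)
  })
}

# ---------------------------------------------------------------------------

#' Swelling and the dry-collagen refractive index
#'
#' The hydrated-fibril refractive index is modeled as the area-weighted
#' average of dry collagen and the water filling the swollen fibril:
#' `n_collagen = (n_dry + delta_A * n_water) / (1 + delta_A)` with
#' `delta_A = A_wet / A_dry - 1`. Given the measured areas and the hydrated
#' index, this inverts exactly for `n_dry`.
#'
#' @param A_dry,A_wet Cross-sectional areas (nm^2) in the dry and hydrated
#'   states.
#' @param n_collagen Hydrated-fibril refractive index.
#' @param n_water Refractive index of water (1.33).
#' @return A `swelling_record` with `A_dry`, `A_wet`, `delta_A`, `n_dry`,
#'   `n_water` and a `shrinkage` flag when `A_wet < A_dry`.
#' @examples
#' swelling_and_dry_index(5000, 10000, 1.43)  # delta_A = 1, n_dry = 1.53
#' @export
swelling_and_dry_index <- function(A_dry, A_wet, n_collagen,
                                   n_water = 1.33) {
  if (A_dry <= 0 || A_wet <= 0) abort("areas must be positive",
                                      class = "rimap_input_error")
  delta_A <- A_wet / A_dry - 1
  n_dry <- n_collagen * (1 + delta_A) - delta_A * n_water
  structure(list(A_dry = A_dry, A_wet = A_wet, delta_A = delta_A,
                 n_dry = n_dry, n_collagen = n_collagen, n_water = n_water,
                 shrinkage = delta_A < 0),
            class = "swelling_record")
}

#' @export
print.swelling_record <- function(x, ...) {
  cat("<swelling_record> delta_A =", round(x$delta_A, 3),
      " n_dry =", round(x$n_dry, 4),
      if (x$shrinkage) " [shrinkage]", "\n")
  invisible(x)
}

#' Cross-sectional area of a height profile
#'
#' Trapezoidal integral of `height - baseline`, clipped at zero, over a
#' monotone lateral grid.
#'
#' @param profile Tibble with `X_nm` (strictly monotone) and a height
#'   column (`Z_smooth`, `Z_med`, `Z_nm` or `height`, first found wins).
#' @param baseline Baseline height (nm) subtracted before integration.
#' @return Area in nm^2.
#' @export
cross_sectional_area <- function(profile, baseline = 0) {
  X <- profile$X_nm
  hcol <- intersect(c("Z_smooth", "Z_med", "Z_nm", "height"),
                    names(profile))[1]
  if (is.na(hcol)) abort("no height column found", class = "rimap_input_error")
  h <- pmax(profile[[hcol]] - baseline, 0)
  dX <- diff(X)
  if (any(dX > 0) && any(dX < 0)) {
    abort("invalid input: X grid must be monotone", class = "rimap_input_error")
  }
  abs(sum((h[-1] + h[-length(h)]) / 2 * dX))
}

# ---------------------------------------------------------------------------

#' Map the refractive index along the fibril axis
#'
#' Slides a window of fixed localization count along the fibril arclength
#' (with the configured overlap). Within each window the sliding-window
#' height is computed for every assumed refractive index, a line is fit, and
#' its intersection with the local AFM height gives the window's refractive
#' index; the per-window experimental error `sigma_n_exp` comes from
#' half-sample resampling of the heights propagated through the
#' intersection.
#'
#' @param cross_sections_by_n Long tibble with columns `n_assumed`,
#'   `loc_id`, `s_nm`, `X_nm`, `Z_nm` (and `x_nm`, `y_nm` for the window
#'   positions): the same molecules refit under each assumed refractive
#'   index of the grid.
#' @param afm_profile Tibble with `s_nm`, `H`, `sigma_H`: local AFM height
#'   along the fibril (interpolated per window).
#' @param window_nlocs Localizations per window.
#' @param overlap_fraction Fractional overlap of consecutive windows
#'   (0.9 steps the window by 10% of its count).
#' @param window_nlocs_inner Localization count of the inner height windows
#'   (default a quarter of `window_nlocs`, at least 10).
#' @param max_window_nm Windows stretching over a longer arclength span
#'   (fibril gaps) are skipped with a flag.
#' @param debris_offset Debris height added to SMLM heights, nm.
#' @param n_resamples Half-sample draws per window and grid point.
#' @param n_draws Monte Carlo draws for the per-window error propagation.
#' @param seed RNG seed.
#' @return A tibble of class `ri_map`: `window`, `s_nm`, `x_nm`, `y_nm`,
#'   `n`, `sigma_n_exp`, `window_nm`, `skipped`.
#' @export
map_ri_along_fibril <- function(cross_sections_by_n, afm_profile,
                                window_nlocs = 100, overlap_fraction = 0.9,
                                window_nlocs_inner = NULL,
                                max_window_nm = Inf, debris_offset = 0,
                                n_resamples = 200, n_draws = 2000,
                                seed = 1) {
  stopifnot(all(c("n_assumed", "loc_id", "s_nm", "X_nm", "Z_nm") %in%
                  names(cross_sections_by_n)))
  if (is.null(window_nlocs_inner)) {
    window_nlocs_inner <- max(10, window_nlocs %/% 4)
  }
  grid <- sort(unique(cross_sections_by_n$n_assumed))
  ref_n <- grid[ceiling(length(grid) / 2)]
  ref <- dplyr::arrange(
    dplyr::filter(cross_sections_by_n, .data$n_assumed == ref_n), .data$s_nm)
  total <- nrow(ref)
  step <- max(1L, round(window_nlocs * (1 - overlap_fraction)))
  n_win <- floor((total - window_nlocs) / step) + 1
  if (n_win < 1) abort("too few localizations for one window",
                       class = "rimap_input_error")
  by_n <- split(cross_sections_by_n, cross_sections_by_n$n_assumed)
  rows <- purrr::map_dfr(seq_len(n_win), function(wi) {
    idx <- (wi - 1) * step + seq_len(window_nlocs)
    ids <- ref$loc_id[idx]
    s_mid <- mean(ref$s_nm[idx])
    extent <- diff(range(ref$s_nm[idx]))
    x_mid <- if ("x_nm" %in% names(ref)) mean(ref$x_nm[idx]) else NA_real_
    y_mid <- if ("y_nm" %in% names(ref)) mean(ref$y_nm[idx]) else NA_real_
    if (extent > max_window_nm) {
      return(tibble(window = wi, s_nm = s_mid, x_nm = x_mid, y_nm = y_mid,
                    n = NA_real_, sigma_n_exp = NA_real_,
                    window_nm = extent, skipped = TRUE))
    }
    heights <- purrr::imap_dfr(by_n, function(cs, nm) {
      sub <- cs[match(ids, cs$loc_id), ]
      sub <- sub[!is.na(sub$X_nm), ]
      hc <- .height_core(sub$X_nm, sub$Z_nm, window_nlocs_inner)
      sig <- resample_height_error(sub, window_nlocs_inner,
                                   n_resamples = n_resamples,
                                   seed = seed + wi)
      tibble(n_assumed = as.numeric(nm), H = hc$H + debris_offset,
             sigma_H = sig)
    })
    H_afm <- approx(afm_profile$s_nm, afm_profile$H, xout = s_mid,
                    rule = 2)$y
    sig_afm <- approx(afm_profile$s_nm, afm_profile$sigma_H, xout = s_mid,
                      rule = 2)$y
    est <- tryCatch(
      suppressWarnings(estimate_refractive_index(
        heights, list(H = H_afm, sigma_H = sig_afm),
        n_draws = n_draws, seed = seed + wi)),
      error = function(e) NULL)
    if (is.null(est)) {
      return(tibble(window = wi, s_nm = s_mid, x_nm = x_mid, y_nm = y_mid,
                    n = NA_real_, sigma_n_exp = NA_real_,
                    window_nm = extent, skipped = TRUE))
    }
    tibble(window = wi, s_nm = s_mid, x_nm = x_mid, y_nm = y_mid,
           n = est$n, sigma_n_exp = est$sigma_n, window_nm = extent,
           skipped = FALSE)
  })
  class(rows) <- c("ri_map", class(rows))
  attr(rows, "window_nlocs") <- window_nlocs
  rows
}

#' Decompose map variance into sample and experimental contributions
#'
#' The variance of the refractive index along the fibril mixes true sample
#' fluctuations with experimental noise; since the two are uncorrelated,
#' `sigma_n_collagen^2 = sigma_n^2 - sigma_n_exp^2` (floored at zero). The
#' decomposition as a function of window size reveals the characteristic
#' length scale of the fluctuations.
#'
#' @param maps List of `ri_map` tibbles computed at different window sizes
#'   (see [map_ri_along_fibril()]).
#' @return Tibble with one row per window size: `window_nlocs`,
#'   `mean_distance_nm` (mean window extent along the fibril), `n_windows`,
#'   `var_total`, `var_exp`, `var_collagen`.
#' @export
variance_decomposition <- function(maps) {
  purrr::map_dfr(maps, function(mp) {
    ok <- mp[!mp$skipped & !is.na(mp$n), ]
    if (nrow(ok) < 3) return(NULL)
    tibble(window_nlocs = attr(mp, "window_nlocs") %||% NA_integer_,
           mean_distance_nm = mean(ok$window_nm),
           n_windows = nrow(ok),
           var_total = var(ok$n),
           var_exp = mean(ok$sigma_n_exp^2),
           var_collagen = max(0, var(ok$n) - mean(ok$sigma_n_exp^2)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
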