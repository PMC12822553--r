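# Coordinate conventions: frames are matrices indexed [i, j] with the x axis
# along rows and y along columns; pixel centers sit at integer indices
# (0-based), lab-frame nm = index * pixel_size_sample; z = 0 at the coverslip.

#' Read a multi-page TIFF stack as integer photon counts
#'
#' @param path TIFF file.
#' @return List of numeric matrices (one per frame).
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    storage.mode(f) <- "double"
    f
  })
}

#' Write a stack of count frames as 16-bit TIFF
#'
#' @param stack List of numeric matrices (counts).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  tiff::writeTIFF(lapply(stack, function(f) pmin(f, 65535) / 65535),
                  path, bits.per.sample = 16L)
  invisible(path)
}

# boxcar running mean along both matrix dimensions, truncated at edges
.boxsmooth <- function(m, w) {
  if (w <= 1) return(m)
  half <- w %/% 2
  run <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    hi <- pmin(seq_len(n) + half, n)
    lo <- pmax(seq_len(n) - half, 1)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2, run)
  t(apply(m, 1, run))
}

#' Detect candidate emitters in a frame
#'
#' The frame is first smoothed with a boxcar filter matched to the extent
#' of the defocused molecule image (the raw defocused psf is ring-shaped
#' and produces many spurious local maxima); candidate centers are then
#' strict local maxima of the smoothed frame exceeding both an absolute
#' intensity threshold and a relative threshold times the frame median.
#' Candidates closer together than `roi_size` pixels are all rejected
#' (overlapping molecule images cannot be fit by the single-emitter model),
#' as are candidates whose ROI would cross the frame border. The result is
#' deterministic given the frame.
#'
#' @param frame Numeric matrix of counts.
#' @param absolute_threshold Minimum smoothed pixel value (counts).
#' @param relative_threshold Minimum smoothed pixel value as a multiple of
#'   the frame median.
#' @param roi_size ROI side length (pixels) used for spacing and borders.
#' @param smooth_px Boxcar width in pixels (default half the ROI).
#' @return Tibble with 0-based pixel indices `px_i`, `px_j` and `value`
#'   (smoothed counts); empty when nothing qualifies.
#' @export
prelocalize <- function(frame, absolute_threshold, relative_threshold = 2,
                        roi_size = 15, smooth_px = NULL) {
  stopifnot(absolute_threshold > 0, relative_threshold > 0)
  if (is.null(smooth_px)) smooth_px <- max(3, roi_size %/% 2)
  nr <- nrow(frame); nc <- ncol(frame)
  sm <- .boxsmooth(frame, smooth_px)
  thr <- max(absolute_threshold, relative_threshold * median(frame))
  # strict local maximum over the 8 neighbors
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sm
  ismax <- sm > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (sm > pad[2:(nr + 1) + di, 2:(nc + 1) + dj] |
                        (sm == pad[2:(nr + 1) + di, 2:(nc + 1) + dj] &
                           (di > 0 | (di == 0 & dj > 0))))
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(px_i = integer(), px_j = integer(), value = numeric()))
  }
  half <- (roi_size - 1) / 2
  keep_border <- idx[, 1] > half & idx[, 1] <= nr - half &
    idx[, 2] > half & idx[, 2] <= nc - half
  idx <- idx[keep_border, , drop = FALSE]
  if (nrow(idx) > 1) {
    d <- as.matrix(stats::dist(idx))
    diag(d) <- Inf
    idx <- idx[apply(d, 1, min) >= roi_size, , drop = FALSE]
  }
  tibble(px_i = as.integer(idx[, 1] - 1L), px_j = as.integer(idx[, 2] - 1L),
         value = sm[idx])
}

#' Cut fitting ROIs around candidate positions
#'
#' @param frame Numeric matrix of counts.
#' @param candidates Tibble from [prelocalize()].
#' @param roi_size Odd ROI side length in pixels.
#' @param frame_index Frame number stored with each ROI.
#' @return List of `molecule_roi` objects (counts + frame position).
#' @export
extract_rois <- function(frame, candidates, roi_size = 15, frame_index = 1L) {
  half <- (roi_size - 1) / 2
  purrr::pmap(candidates, function(px_i, px_j, ...) {
    ri <- (px_i + 1) + (-half:half)
    rj <- (px_j + 1) + (-half:half)
    structure(list(counts = frame[ri, rj],
                   center_px = c(px_i, px_j),
                   frame = as.integer(frame_index)),
              class = "molecule_roi")
  })
}

# ---------------------------------------------------------------------------
# psf z-table: radial profiles tabulated on a z grid for fast repeated fits
# at fixed (n_layer, H, defocus). Linear interpolation in z and r.
.psf_ztable <- function(system, sample, z_range = NULL, dz = 4) {
  if (is.null(z_range)) {
    z_range <- c(0, max(400, sample$thickness + 200))
  }
  key <- paste("zt", system$numerical_aperture, system$emission_wavelength,
               system$n_immersion, system$n_ambient, system$defocus,
               paste(names(system$zernike_terms),
                     unlist(system$zernike_terms), collapse = ","),
               sample$n_layer, sample$thickness,
               z_range[1], z_range[2], dz, sep = "|")
  hit <- .rimap_cache[[key]]
  if (!is.null(hit)) return(hit)
  zs <- seq(z_range[1], z_range[2], by = dz)
  r_fit <- 2600   # covers a 15 px ROI with sub-pixel offsets
  rg <- .pupil_quadrature(system, r_max = r_fit)$r
  profs <- vapply(zs, function(z) {
    .psf_radial_profile(system, sample$n_layer, sample$thickness, z,
                        r_max = r_fit)$I
  }, numeric(length(rg)))
  out <- list(r = rg, z = zs, I = profs)
  .rimap_cache[[key]] <- out
  out
}

# shape (per-pixel fraction of total flux) at (x0, y0, z) from a z-table
.shape_from_ztable <- function(zt, system, x0, y0, z, roi_size) {
  z <- min(max(z, zt$z[1]), zt$z[length(zt$z)])
  iz <- findInterval(z, zt$z, rightmost.closed = TRUE)
  iz <- min(iz, length(zt$z) - 1)
  wz <- (z - zt$z[iz]) / (zt$z[iz + 1] - zt$z[iz])
  prof <- list(r = zt$r, I = (1 - wz) * zt$I[, iz] + wz * zt$I[, iz + 1])
  .render_from_profile(prof, system, x0 = x0, y0 = y0, N = 1, BG = 0,
                       roi_size = roi_size)
}

# Poisson log-likelihood profile over (N, BG) at fixed shape, by damped
# Newton; returns list(N, BG, ll).
.profile_nb <- function(y, p, N0, B0) {
  N <- max(N0, 1); B <- max(B0, 1e-3)
  for (it in 1:25) {
    mu <- N * p + B
    mu[mu < 1e-12] <- 1e-12
    r <- y / mu - 1
    gN <- sum(p * r); gB <- sum(r)
    w <- y / mu^2
    hNN <- -sum(p^2 * w); hNB <- -sum(p * w); hBB <- -sum(w)
    det <- hNN * hBB - hNB^2
    if (!is.finite(det) || abs(det) < 1e-300) break
    dN <- -(hBB * gN - hNB * gB) / det
    dB <- -(-hNB * gN + hNN * gB) / det
    step <- 1
    if (N + dN < 0) step <- min(step, -0.9 * N / dN)
    if (B + dB < 0) step <- min(step, -0.9 * B / dB)
    N <- N + step * dN; B <- B + step * dB
    if (abs(step * dN) < 1e-8 * (N + 1) && abs(step * dB) < 1e-8 * (B + 1))
      break
  }
  mu <- N * p + B
  mu[mu < 1e-12] <- 1e-12
  list(N = N, B = B, ll = sum(y * log(mu) - mu))
}

.ll_saturated <- function(y) {
  yl <- y[y > 0]
  sum(yl * log(yl) - yl) - sum(y[y <= 0] * 0)
}

#' Fit the molecule-image model to an ROI by Poisson maximum likelihood
#'
#' Maximizes the Poisson log-likelihood of the layered-sample psf model over
#' lateral position, axial position, photon count and background, at fixed
#' assumed layer refractive index and thickness. The fit quality is the
#' log-likelihood ratio `llr = 2 (LL_saturated - LL_fit)`; localizations
#' with large `llr` (conventionally >= 600 on 15 x 15 px) are poorly modeled
#' and should be filtered downstream.
#'
#' @param roi A `molecule_roi` from [extract_rois()], or a bare counts matrix.
#' @param system An [optical_system()].
#' @param sample A [layered_sample()]; its `n_layer` is the refractive index
#'   assumed for this fit.
#' @param init Optional [emitter_state()] initialization. By default x, y
#'   start at the ROI centroid, N at the background-subtracted ROI sum, BG at
#'   the ROI border median, and z at 0.
#' @param fix_xy If `TRUE`, the lateral position is held at its
#'   initialization and only (z, N, BG) are optimized; used when refitting
#'   the same molecules under different assumed refractive indices.
#' @param z_range Axial search range in nm.
#' @return One-row tibble: `frame, x_nm, y_nm, z_nm, photons, background,
#'   llr, converged`.
#' @export
fit_molecule <- function(roi, system, sample, init = NULL, fix_xy = FALSE,
                         z_range = NULL) {
  if (is.matrix(roi)) {
    roi <- structure(list(counts = roi,
                          center_px = c((nrow(roi) - 1) / 2,
                                        (ncol(roi) - 1) / 2),
                          frame = NA_integer_),
                     class = "molecule_roi")
  }
  y <- roi$counts
  if (any(y < 0)) abort("invalid input: negative counts",
                        class = "rimap_input_error")
  roi_size <- nrow(y)
  px <- system$pixel_size_sample
  zt <- .psf_ztable(system, sample, z_range = z_range)
  yv <- as.vector(y)
  border <- c(y[1, ], y[roi_size, ], y[, 1], y[, roi_size])
  B0 <- median(border)
  N0 <- max(sum(y) - B0 * length(y), 10)
  if (is.null(init)) {
    half <- (roi_size - 1) / 2
    cc <- (seq_len(roi_size) - 1 - half) * px
    w <- pmax(y - B0, 0)
    x0 <- sum(w * matrix(cc, roi_size, roi_size)) / sum(w)
    y0 <- sum(w * t(matrix(cc, roi_size, roi_size))) / sum(w)
    z0 <- 0
  } else {
    x0 <- init$lateral_offset[1]
    y0 <- init$lateral_offset[2]
    z0 <- init$axial_position
    if (init$signal_photons > 0) N0 <- init$signal_photons
    if (init$background_per_pixel > 0) B0 <- init$background_per_pixel
  }
  nb <- list(N = N0, B = B0)
  negll <- function(par) {
    p <- .shape_from_ztable(zt, system, par[1], par[2], par[3], roi_size)
    f <- .profile_nb(yv, as.vector(p), nb$N, nb$B)
    nb <<- f
    -f$ll
  }
  if (fix_xy) {
    lo <- zt$z[1]; hi <- zt$z[length(zt$z)]
    opt <- optimize(function(z) negll(c(x0, y0, z)), c(lo, hi), tol = 1e-2)
    par <- c(x0, y0, opt$minimum)
    conv <- TRUE
    ll <- -opt$objective
  } else {
    o <- optim(c(x0, y0, z0), negll, method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = 180))
    par <- o$par
    conv <- o$convergence == 0
    ll <- -o$value
  }
  f <- .profile_nb(yv,
                   as.vector(.shape_from_ztable(zt, system, par[1], par[2],
                                                par[3], roi_size)),
                   nb$N, nb$B)
  llr <- 2 * (.ll_saturated(yv) - f$ll)
  tibble(frame = roi$frame,
         x_nm = roi$center_px[1] * px + par[1],
         y_nm = roi$center_px[2] * px + par[2],
         z_nm = min(max(par[3], zt$z[1]), zt$z[length(zt$z)]),
         photons = f$N, background = f$B,
         llr = max(llr, 0), converged = conv)
}

#' Fit a batch of ROIs
#'
#' @param rois List of `molecule_roi` objects.
#' @inheritParams fit_molecule
#' @param init_positions Optional tibble with columns `x_nm`, `y_nm` (and
#'   optionally `z_nm`) giving per-ROI initializations in lab coordinates;
#'   combined with `fix_xy = TRUE` this refits only the axial position.
#' @return Tibble of localizations, one row per ROI.
#' @export
fit_rois <- function(rois, system, sample, fix_xy = FALSE,
                     init_positions = NULL, z_range = NULL) {
  px <- system$pixel_size_sample
  purrr::imap_dfr(rois, function(roi, k) {
    init <- NULL
    if (!is.null(init_positions)) {
      init <- emitter_state(
        lateral_offset = c(init_positions$x_nm[k] - roi$center_px[1] * px,
                           init_positions$y_nm[k] - roi$center_px[2] * px),
        axial_position = if ("z_nm" %in% names(init_positions))
          init_positions$z_nm[k] else 0,
        signal_photons = 0, background_per_pixel = 0)
    }
    fit_molecule(roi, system, sample, init = init, fix_xy = fix_xy,
                 z_range = z_range)
  })
}

#' Localize a full image stack
#'
#' Runs [prelocalize()] on every frame, cuts ROIs and fits each with
#' [fit_molecule()].
#'
#' @param stack List of count matrices (frames).
#' @inheritParams fit_molecule
#' @param absolute_threshold,relative_threshold Passed to [prelocalize()].
#' @param keep_rois If `TRUE`, the extracted ROIs are attached as attribute
#'   `rois` so the same molecules can be refit under other assumed
#'   refractive indices.
#' @return Tibble of localizations.
#' @export
localize_stack <- function(stack, system, sample, absolute_threshold,
                           relative_threshold = 2, keep_rois = FALSE,
                           z_range = NULL) {
  all_rois <- list()
  out <- purrr::imap_dfr(stack, function(frame, fi) {
    cand <- prelocalize(frame, absolute_threshold, relative_threshold,
                        roi_size = system$roi_size)
    if (nrow(cand) == 0) return(NULL)
    rois <- extract_rois(frame, cand, roi_size = system$roi_size,
                         frame_index = fi)
    if (keep_rois) all_rois[[length(all_rois) + 1]] <<- rois
    fit_rois(rois, system, sample, z_range = z_range)
  })
  if (keep_rois) attr(out, "rois") <- purrr::flatten(all_rois)
  out
}

#' Merge repeated blinks of the same fluorophore
#'
#' Links drift-corrected localizations that reappear within
#' `linking_radius` across at most `max_gap` dark frames, and summarizes
#' each chain by its per-axis mean and standard error of the mean (the
#' localization precision of the merged signal).
#'
#' @param localizations Tibble with `frame`, `x_nm`, `y_nm`, `z_nm`.
#' @param linking_radius Lateral linking radius in nm.
#' @param max_gap Maximum number of intervening dark frames.
#' @return Tibble with one row per merged fluorophore: mean positions,
#'   per-axis `sem_*` (NA when `n_observations == 1`), and `n_observations`.
#' @export
merge_blinks <- function(localizations, linking_radius = 100, max_gap = 3) {
  locs <- dplyr::arrange(localizations, .data$frame)
  n <- nrow(locs)
  id <- integer(n)
  open_id <- integer(0); open_x <- numeric(0); open_y <- numeric(0)
  open_frame <- integer(0)
  next_id <- 0L
  for (k in seq_len(n)) {
    fr <- locs$frame[k]
    live <- which(fr - open_frame <= max_gap + 1L)
    assigned <- FALSE
    if (length(live)) {
      dd <- sqrt((open_x[live] - locs$x_nm[k])^2 +
                   (open_y[live] - locs$y_nm[k])^2)
      j <- live[which.min(dd)]
      if (min(dd) <= linking_radius) {
        id[k] <- open_id[j]
        open_x[j] <- locs$x_nm[k]; open_y[j] <- locs$y_nm[k]
        open_frame[j] <- fr
        assigned <- TRUE
      }
    }
    if (!assigned) {
      next_id <- next_id + 1L
      id[k] <- next_id
      open_id <- c(open_id, next_id)
      open_x <- c(open_x, locs$x_nm[k]); open_y <- c(open_y, locs$y_nm[k])
      open_frame <- c(open_frame, fr)
    }
  }
  locs$merge_id <- id
  out <- dplyr::summarise(
    dplyr::group_by(locs, .data$merge_id),
    sem_x = if (dplyr::n() > 1) sd(.data$x_nm) / sqrt(dplyr::n()) else NA_real_,
    sem_y = if (dplyr::n() > 1) sd(.data$y_nm) / sqrt(dplyr::n()) else NA_real_,
    sem_z = if (dplyr::n() > 1) sd(.data$z_nm) / sqrt(dplyr::n()) else NA_real_,
    x_nm = mean(.data$x_nm), y_nm = mean(.data$y_nm), z_nm = mean(.data$z_nm),
    n_observations = dplyr::n(), .groups = "drop")
  out[, c("merge_id", "x_nm", "y_nm", "z_nm", "sem_x", "sem_y", "sem_z",
          "n_observations")]
}

#' Write / read localization tables
#'
#' CSV with the column schema
#' `frame,x_nm,y_nm,z_nm,photons,background,llr,converged`.
#'
#' @param localizations Localization tibble.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_localizations <- function(localizations, path) {
  cols <- c("frame", "x_nm", "y_nm", "z_nm", "photons", "background",
            "llr", "converged")
  write.csv(localizations[intersect(cols, names(localizations))], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  as_tibble(read.csv(path))
}
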