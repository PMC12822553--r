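# Ground-truth synthetic data: surface-labeled half-cylindrical fibril
# phantoms, dSTORM-like blinking image stacks with fiducials and drift, and
# matching AFM height maps. Rendering uses the same planar-layer forward
# model as fitting, so recovery tests isolate pipeline correctness from
# model misspecification (a deliberate idealization).

#' Define a fibril phantom
#'
#' A half-cylindrical fibril lying on the coverslip along a planar axis,
#' surface-labeled at a fixed density, with unspecifically bound dyes on the
#' surrounding glass.
#'
#' @param length Fibril length in nm.
#' @param radius_wet,radius_dry Hydrated and dry crest radii in nm (the
#'   hydrated radius is the one imaged by SMLM; swelling
#'   `delta_A = (radius_wet / radius_dry)^2 - 1` for a self-similar
#'   cross-section).
#' @param n_true Refractive-index profile: a single number or a function of
#'   arclength s (nm).
#' @param curvature Axis curvature in 1/nm (0 = straight; an arc otherwise).
#' @param label_density Surface label density, um^-2.
#' @param glass_density Density of unspecifically glass-bound labels, um^-2 (sparse).
#' @param label_offset Normal offset of the dye from the surface (antibody
#'   linker), nm.
#' @param field_nm Length-2 field of view (nm) into which the phantom is
#'   centered.
#' @return A `fibril_phantom`.
#' @export
fibril_phantom <- function(length = 6000, radius_wet = 100,
                           radius_dry = 60, n_true = 1.43, curvature = 0,
                           label_density = 400, glass_density = 1.5,
                           label_offset = 0, field_nm = c(7680, 7680)) {
  stopifnot(radius_wet >= 0, radius_dry > 0, length > 0)
  n_fun <- if (is.function(n_true)) n_true else function(s) rep(n_true,
                                                                length(s))
  nv <- n_fun(seq(0, length, by = 100))
  if (any(nv < 1.33 | nv > 1.80)) {
    abort("n_true must stay within [1.33, 1.80]", class = "rimap_input_error")
  }
  structure(list(length = length, radius_wet = radius_wet,
                 radius_dry = radius_dry, n_fun = n_fun,
                 curvature = curvature, label_density = label_density,
                 glass_density = glass_density, label_offset = label_offset,
                 field_nm = field_nm),
            class = "fibril_phantom")
}

# axis point + unit tangent/normal at arclength s (axis centered in field,
# running along x for curvature 0, or along a circular arc)
.phantom_axis <- function(phantom, s) {
  cx <- phantom$field_nm[1] / 2
  cy <- phantom$field_nm[2] / 2
  L <- phantom$length
  if (phantom$curvature == 0) {
    list(x = cx - L / 2 + s, y = rep(cy, length(s)),
         tx = rep(1, length(s)), ty = rep(0, length(s)))
  } else {
    R <- 1 / phantom$curvature
    th <- (s - L / 2) / R
    list(x = cx + R * sin(th), y = cy + R * (1 - cos(th)),
         tx = cos(th), ty = sin(th))
  }
}

#' Generate ground-truth emitters for a phantom
#'
#' Emitters are placed by a Poisson point process on the upper
#' half-cylinder surface (uniform in arclength and polar angle, i.e.
#' uniform per unit area) and on the surrounding glass. Each emitter
#' carries its true position, arclength, and local refractive index.
#'
#' @param phantom A [fibril_phantom()].
#' @param seed RNG seed.
#' @return Tibble: `id`, `x_nm`, `y_nm`, `z_nm`, `s_nm`, `X_nm`, `n_true`,
#'   `on_glass`.
#' @export
generate_phantom <- function(phantom, seed = 1) {
  withr_seed(seed, {
    R <- phantom$radius_wet + phantom$label_offset
    area_um2 <- pi * R * phantom$length / 1e6
    n_fib <- rpois(1, phantom$label_density * area_um2)
    s <- runif(n_fib, 0, phantom$length)
    th <- runif(n_fib, 0, pi)             # angle from +X side over the crest
    ax <- .phantom_axis(phantom, s)
    X <- R * cos(th)
    z <- R * sin(th)
    fib <- tibble(x_nm = ax$x - X * ax$ty, y_nm = ax$y + X * ax$tx,
                  z_nm = z, s_nm = s, X_nm = X,
                  n_true = phantom$n_fun(s), on_glass = FALSE)
    glass_area_um2 <- prod(phantom$field_nm) / 1e6
    n_gl <- rpois(1, phantom$glass_density * glass_area_um2)
    gl <- tibble(x_nm = runif(n_gl, 0, phantom$field_nm[1]),
                 y_nm = runif(n_gl, 0, phantom$field_nm[2]),
                 z_nm = 0, s_nm = NA_real_, X_nm = NA_real_,
                 n_true = NA_real_, on_glass = TRUE)
    # keep glass dyes clear of the fibril footprint
    if (n_gl > 0 && n_fib > 0) {
      axg <- .phantom_axis(phantom, seq(0, phantom$length, by = 50))
      near <- vapply(seq_len(n_gl), function(i) {
        min((gl$x_nm[i] - axg$x)^2 + (gl$y_nm[i] - axg$y)^2) < (R + 50)^2
      }, logical(1))
      gl <- gl[!near, ]
    }
    out <- dplyr::bind_rows(fib, gl)
    out$id <- seq_len(nrow(out))
    dplyr::relocate(out, "id")
  })
}

#' Define the acquisition model
#'
#' Blinking is a two-state Markov chain per emitter (geometric on-times);
#' photons per on-frame are log-normal. Defaults target the dSTORM regime
#' of roughly 10^3 detected photons per localization.
#'
#' @param frames Number of frames.
#' @param frame_px Frame size in pixels (length-2).
#' @param mean_photons Mean photons per on-frame.
#' @param photons_sdlog Log-sd of the per-frame photon count.
#' @param p_on Per-frame off-to-on switching probability.
#' @param mean_on_frames Mean on-state duration in frames.
#' @param background Mean background photons per pixel per frame.
#' @param drift_per_frame Linear drift velocity (nm/frame, length-2).
#' @param drift_rw_sd Random-walk drift step sd (nm/frame).
#' @param fiducials Tibble with `x_nm`, `y_nm`, `photons`; `NULL` places
#'   two default beads.
#' @param seed RNG seed for the acquisition randomness.
#' @return An `acquisition_model`.
#' @export
acquisition_model <- function(frames = 400, frame_px = c(48, 48),
                              mean_photons = 1000, photons_sdlog = 0.35,
                              p_on = 0.004, mean_on_frames = 1.5,
                              background = 10,
                              drift_per_frame = c(0.05, -0.03),
                              drift_rw_sd = 0.2, fiducials = NULL,
                              seed = 1) {
  stopifnot(frames >= 1, p_on >= 0, mean_on_frames >= 1, background >= 0)
  structure(list(frames = as.integer(frames), frame_px = frame_px,
                 mean_photons = mean_photons, photons_sdlog = photons_sdlog,
                 p_on = p_on, mean_on_frames = mean_on_frames,
                 background = background,
                 drift_per_frame = drift_per_frame,
                 drift_rw_sd = drift_rw_sd, fiducials = fiducials,
                 seed = seed),
            class = "acquisition_model")
}

# drift trajectory (nm) per frame: linear + random walk
.drift_trajectory <- function(acq) {
  f <- acq$frames
  rw_x <- cumsum(rnorm(f, 0, acq$drift_rw_sd))
  rw_y <- cumsum(rnorm(f, 0, acq$drift_rw_sd))
  tibble(frame = seq_len(f),
         dx = acq$drift_per_frame[1] * (seq_len(f) - 1) + rw_x - rw_x[1],
         dy = acq$drift_per_frame[2] * (seq_len(f) - 1) + rw_y - rw_y[1])
}

# stamp a psf (from a cached radial profile) into a frame, in place
.stamp <- function(frame, prof, system, x_nm, y_nm, N, stamp_px) {
  px <- system$pixel_size_sample
  ci <- round(x_nm / px); cj <- round(y_nm / px)
  half <- (stamp_px - 1) / 2
  ri <- (ci - half):(ci + half)
  rj <- (cj - half):(cj + half)
  ok_i <- ri >= 0 & ri < nrow(frame)
  ok_j <- rj >= 0 & rj < ncol(frame)
  if (!any(ok_i) || !any(ok_j)) return(frame)
  img <- .render_from_profile(prof, system, x0 = x_nm - ci * px,
                              y0 = y_nm - cj * px, N = N, BG = 0,
                              roi_size = stamp_px)
  frame[ri[ok_i] + 1, rj[ok_j] + 1] <-
    frame[ri[ok_i] + 1, rj[ok_j] + 1] + img[ok_i, ok_j]
  frame
}

#' Render a blinking SMLM image stack for a phantom
#'
#' Per frame, the emitters switching on are drawn from the blinking model
#' and rendered through the layered-sample psf with their local true
#' refractive index and height (the local layer thickness equals the
#' emitter height over the crest region); drift shifts all positions;
#' fiducial beads are rendered in every frame; Poisson noise is applied.
#'
#' @param emitters Tibble from [generate_phantom()].
#' @param acq An [acquisition_model()].
#' @param system An [optical_system()].
#' @param phantom The [fibril_phantom()] (provides the layer thickness used
#'   for fibril emitters).
#' @return List: `stack` (list of count matrices), `truth` (tibble of every
#'   rendered burst), `fiducial_truth`, `drift`.
#' @export
render_smlm_stack <- function(emitters, acq, system, phantom = NULL) {
  withr_seed(acq$seed, {
    px <- system$pixel_size_sample
    dims <- acq$frame_px
    # stamps extend beyond the fitting ROI so extracted ROIs never see the
    # rendering truncation boundary
    stamp_px <- system$roi_size + 6L
    fid <- acq$fiducials
    if (is.null(fid)) {
      fx <- dims[1] * px
      fid <- tibble(x_nm = c(0.22, 0.78) * fx,
                    y_nm = c(0.22, 0.78) * dims[2] * px,
                    photons = 2e4)
    }
    H_layer <- if (is.null(phantom)) max(emitters$z_nm) else
      phantom$radius_wet
    # per-emitter psf profiles (z and local n fixed per emitter)
    prof_cache <- new.env(parent = emptyenv())
    emitter_prof <- function(k) {
      key <- if (emitters$on_glass[k]) "glass" else as.character(k)
      p <- prof_cache[[key]]
      if (is.null(p)) {
        e <- emitters[k, ]
        if (e$on_glass) {
          p <- .psf_radial_profile(system, system$n_ambient, 0, 0,
                                   r_max = 2600)
        } else {
          p <- .psf_radial_profile(system, e$n_true,
                                   min(H_layer, max(e$z_nm, 1)), e$z_nm,
                                   r_max = 2600)
        }
        prof_cache[[key]] <- p
      }
      p
    }
    fid_prof <- .psf_radial_profile(system, system$n_ambient, 0, 0,
                                    r_max = 2600)
    drift <- .drift_trajectory(acq)
    n_em <- nrow(emitters)
    on <- rep(FALSE, n_em)
    p_off <- 1 / acq$mean_on_frames
    meanlog <- log(acq$mean_photons) - acq$photons_sdlog^2 / 2
    # density guard: warn when active emitters routinely overlap
    truth <- vector("list", acq$frames)
    stack <- vector("list", acq$frames)
    overlap_frames <- 0L
    for (f in seq_len(acq$frames)) {
      switch_on <- !on & runif(n_em) < acq$p_on
      on <- (on & runif(n_em) >= p_off) | switch_on
      act <- which(on)
      frame <- matrix(0, dims[1], dims[2])
      rows <- NULL
      if (length(act)) {
        xs <- emitters$x_nm[act] + drift$dx[f]
        ys <- emitters$y_nm[act] + drift$dy[f]
        if (length(act) > 1) {
          dmin <- min(stats::dist(cbind(xs, ys)))
          if (dmin < stamp_px * px) overlap_frames <- overlap_frames + 1L
        }
        Ns <- rlnorm(length(act), meanlog, acq$photons_sdlog)
        for (a in seq_along(act)) {
          frame <- .stamp(frame, emitter_prof(act[a]), system,
                          xs[a], ys[a], Ns[a], stamp_px)
        }
        rows <- tibble(frame = f, id = emitters$id[act],
                       x_nm = xs, y_nm = ys, z_nm = emitters$z_nm[act],
                       n_true = emitters$n_true[act], photons = Ns)
      }
      for (b in seq_len(nrow(fid))) {
        frame <- .stamp(frame, fid_prof, system,
                        fid$x_nm[b] + drift$dx[f],
                        fid$y_nm[b] + drift$dy[f], fid$photons[b], stamp_px)
      }
      stack[[f]] <- matrix(rpois(length(frame), frame + acq$background),
                           dims[1], dims[2])
      truth[[f]] <- rows
    }
    if (overlap_frames > 0.25 * acq$frames) {
      warn(sprintf("emitter density causes ROI overlap in %d/%d frames",
                   overlap_frames, acq$frames))
    }
    list(stack = stack,
         truth = dplyr::bind_rows(truth),
         fiducial_truth = fid,
         drift = drift)
  })
}

#' Render an AFM height map of a phantom
#'
#' Samples the phantom's upper surface (half-cylinder of the state's
#' radius) onto a regular grid, then adds Gaussian height noise and
#' per-line tilts.
#'
#' @param phantom A [fibril_phantom()].
#' @param pixel_size Grid pixel size, nm (default 39).
#' @param noise_sigma Gaussian height noise sd, nm.
#' @param line_tilt_sd Sd of the per-line tilt slopes (nm per pixel).
#' @param line_offset_sd Sd of the per-line offsets (nm).
#' @param state Which radius to use, `"wet"` or `"dry"`.
#' @param seed RNG seed.
#' @return An [afm_map()] with the true glass mask attached.
#' @export
render_afm_map <- function(phantom, pixel_size = 39, noise_sigma = 0,
                           line_tilt_sd = 0, line_offset_sd = 0,
                           state = c("wet", "dry"), seed = 1) {
  state <- match.arg(state)
  if (pixel_size <= 0) abort("pixel_size must be > 0",
                             class = "rimap_input_error")
  R <- if (state == "wet") phantom$radius_wet else phantom$radius_dry
  nx <- ceiling(phantom$field_nm[1] / pixel_size)
  ny <- ceiling(phantom$field_nm[2] / pixel_size)
  xi <- (seq_len(nx) - 1) * pixel_size
  yj <- (seq_len(ny) - 1) * pixel_size
  # distance of each grid point to the axis polyline
  axg <- .phantom_axis(phantom, seq(0, phantom$length, by = pixel_size / 2))
  h <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {
    d2 <- vapply(seq_len(nx), function(i) {
      min((xi[i] - axg$x)^2 + (yj[j] - axg$y)^2)
    }, numeric(1))
    inside <- d2 < R^2
    h[inside, j] <- sqrt(R^2 - d2[inside])
  }
  mask <- h == 0
  withr_seed(seed, {
    if (noise_sigma > 0) h <- h + rnorm(length(h), 0, noise_sigma)
    if (line_tilt_sd > 0 || line_offset_sd > 0) {
      tilts <- rnorm(nx, 0, line_tilt_sd)
      offs <- rnorm(nx, 0, line_offset_sd)
      h <- h + offs + tilts %o% seq_len(ny)
    }
    afm_map(h, pixel_size = pixel_size, state = state, glass_mask = mask)
  })
}
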