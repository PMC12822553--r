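#' Fisher information for the sample refractive index
#'
#' Computes the scalar Fisher information carried by a single-molecule image
#' about the layer refractive index n, at known layer thickness, photon
#' count, and background:
#' `FI = sum_xy (1 / I_xy) (dI_xy / dn)^2`
#' for Poisson-distributed pixel counts. The derivative is taken at fixed
#' H, N, BG and instrument parameters, by central finite differences.
#'
#' @param system An [optical_system()].
#' @param sample A [layered_sample()]; its `n_layer` is the evaluation point.
#' @param emitter An [emitter_state()].
#' @param step Finite-difference step in refractive-index units.
#' @param roi_size Optional ROI override (odd).
#' @param check_step If `TRUE`, recompute at `step / 2` and warn when the two
#'   estimates differ by more than 0.5% (Richardson consistency).
#'
#' @return Nonnegative Fisher information. When `sample$thickness == 0` the
#'   image does not depend on n; the function returns `0` with attribute
#'   `n_unidentifiable = TRUE`.
#' @examples
#' \donttest{
#' fisher_information_n(optical_system(), layered_sample(1.437, 138),
#'                      emitter_state(axial_position = 138,
#'                                    signal_photons = 123648,
#'                                    background_per_pixel = 123648 / 110))
#' }
#' @export
fisher_information_n <- function(system, sample, emitter, step = 1e-4,
                                 roi_size = NULL, check_step = FALSE) {
  stopifnot(inherits(system, "optical_system"),
            inherits(sample, "layered_sample"),
            inherits(emitter, "emitter_state"))
  if (sample$thickness == 0) {
    return(structure(0, n_unidentifiable = TRUE))
  }
  fi <- .fi_eval(system, sample, emitter, step, roi_size)
  if (check_step) {
    fi2 <- .fi_eval(system, sample, emitter, step / 2, roi_size)
    if (abs(fi - fi2) > 5e-3 * fi2) {
      warn(sprintf("Fisher information step check: h and h/2 differ by %.2f%%",
                   100 * abs(fi - fi2) / fi2))
    }
  }
  fi
}

.fi_eval <- function(system, sample, emitter, step, roi_size = NULL,
                     param = "n") {
  sp <- sm <- sample
  ep <- em <- emitter
  if (param == "n") {
    sp$n_layer <- sample$n_layer + step
    sm$n_layer <- sample$n_layer - step
  } else if (param == "z") {
    ep$axial_position <- emitter$axial_position + step
    em$axial_position <- emitter$axial_position - step
  } else if (param == "H") {
    sp$thickness <- sample$thickness + step
    sm$thickness <- sample$thickness - step
  } else if (param == "x") {
    ep$lateral_offset <- emitter$lateral_offset + c(step, 0)
    em$lateral_offset <- emitter$lateral_offset - c(step, 0)
  }
  i0 <- compute_molecule_image(system, sample, emitter, roi_size = roi_size)
  ip <- compute_molecule_image(system, sp, ep, roi_size = roi_size)
  im <- compute_molecule_image(system, sm, em, roi_size = roi_size)
  dI <- (unclass(ip) - unclass(im)) / (2 * step)
  I <- unclass(i0)
  if (any(I <= 0)) {
    if (any(dI[I <= 0] != 0)) {
      abort("numerical degeneracy: zero-intensity pixel with nonzero derivative",
            class = "rimap_degenerate_error")
    }
    dI <- dI[I > 0]
    I <- I[I > 0]
  }
  sum(dI^2 / I)
}

#' Cramer-Rao bound on the refractive-index precision from SMLM
#'
#' The best precision any unbiased estimator can reach for the layer
#' refractive index given the imaging model: `delta_n = 1 / sqrt(FI)`.
#'
#' @inheritParams fisher_information_n
#' @return The CRLB (dimensionless). When the Fisher information is zero
#'   (e.g. no layer), returns `Inf` with attribute `unbounded = TRUE` so
#'   batch sweeps complete without exceptions.
#' @examples
#' \donttest{
#' # the worked single-fibril configuration
#' delta_n_smlm(optical_system(), layered_sample(1.437, 138),
#'              emitter_state(axial_position = 138,
#'                            signal_photons = 123648,
#'                            background_per_pixel = 123648 / 110))
#' }
#' @export
delta_n_smlm <- function(system, sample, emitter, step = 1e-4,
                         roi_size = NULL) {
  fi <- fisher_information_n(system, sample, emitter, step = step,
                             roi_size = roi_size)
  if (fi == 0) {
    return(structure(Inf, unbounded = TRUE))
  }
  1 / sqrt(fi)
}

#' AFM height uncertainty
#'
#' @param delta_z Standard error of the AFM height measurement, nm (>= 0).
#' @return An `afm_uncertainty` object.
#' @export
afm_uncertainty <- function(delta_z = 1) {
  if (delta_z < 0) abort("delta_z must be >= 0", class = "rimap_input_error")
  structure(list(delta_z = delta_z), class = "afm_uncertainty")
}

#' Refractive-index error induced by the AFM height error
#'
#' Propagates the AFM height uncertainty into the refractive-index estimate:
#' noise-free molecule images are computed at thicknesses `H +/- delta_z`,
#' and for each the refractive index `n_hat` minimizing the squared image
#' difference to images modeled at thickness `H` is found by bounded scalar
#' minimization. The reported error is the symmetrized
#' `(|n - n_hat_minus| + |n - n_hat_plus|) / 2`.
#'
#' @inheritParams fisher_information_n
#' @param afm An [afm_uncertainty()] (or a plain nonnegative number, nm).
#' @param bounds Search interval for the fitted refractive index.
#' @param tol Optimizer tolerance on n.
#' @return Nonnegative refractive-index error, with the two one-sided
#'   estimates attached as attributes `n_hat_minus` / `n_hat_plus`.
#' @examples
#' \donttest{
#' delta_n_afm(optical_system(), layered_sample(1.437, 100),
#'             emitter_state(axial_position = 100, signal_photons = 1e5,
#'                           background_per_pixel = 1e3),
#'             afm_uncertainty(1))
#' }
#' @export
delta_n_afm <- function(system, sample, emitter, afm = afm_uncertainty(1),
                        bounds = c(1.30, 1.60), tol = 1e-6, roi_size = NULL) {
  if (is.numeric(afm)) afm <- afm_uncertainty(afm)
  dz <- afm$delta_z
  if (dz == 0) {
    return(structure(0, n_hat_minus = sample$n_layer,
                     n_hat_plus = sample$n_layer))
  }
  n0 <- sample$n_layer
  H <- sample$thickness
  # surface-labeled dyes ride the layer top: a sample of thickness
  # H +/- dz carries its emitter at that same height
  dz_emitter <- emitter$axial_position - H
  img_at <- function(n, H_use) {
    unclass(compute_molecule_image(
      system, layered_sample(n, H_use),
      emitter_state(emitter$lateral_offset, max(H_use + dz_emitter, 0),
                    emitter$signal_photons, emitter$background_per_pixel),
      roi_size = roi_size))
  }
  fit_one <- function(H_true) {
    target <- img_at(n0, H_true)
    obj <- function(nf) sum((target - img_at(nf, H))^2)
    opt <- optimize(obj, bounds, tol = tol)
    edge <- min(opt$minimum - bounds[1], bounds[2] - opt$minimum)
    if (edge < 10 * tol) {
      scan <- vapply(seq(bounds[1], bounds[2], length.out = 31), obj,
                     numeric(1))
      abort(paste0("delta_n_afm optimization hit the search bound at n = ",
                   signif(opt$minimum, 6)),
            class = "rimap_optim_error", body = list(scan = scan))
    }
    opt$minimum
  }
  n_plus <- fit_one(H + dz)
  n_minus <- fit_one(H - dz)
  structure(0.5 * (abs(n0 - n_minus) + abs(n0 - n_plus)),
            n_hat_minus = n_minus, n_hat_plus = n_plus)
}

#' Combine the SMLM and AFM error contributions
#'
#' The two error sources are independent, so their variances add:
#' `delta_n_total = sqrt(smlm^2 + afm^2)`.
#'
#' @param smlm,afm Nonnegative error contributions (dimensionless).
#' @return A `precision_budget` with fields `delta_n_smlm`, `delta_n_afm`,
#'   `delta_n_total`.
#' @examples
#' total_delta_n(3e-3, 4e-3)  # 5e-3
#' @export
total_delta_n <- function(smlm, afm) {
  if (is.na(smlm) || is.na(afm) || smlm < 0 || afm < 0) {
    abort("error contributions must be nonnegative numbers",
          class = "rimap_input_error")
  }
  structure(list(delta_n_smlm = as.numeric(smlm),
                 delta_n_afm = as.numeric(afm),
                 delta_n_total = sqrt(smlm^2 + afm^2)),
            class = "precision_budget")
}

#' @export
print.precision_budget <- function(x, ...) {
  cat("<precision_budget> smlm", signif(x$delta_n_smlm, 4),
      " afm", signif(x$delta_n_afm, 4),
      " total", signif(x$delta_n_total, 4), "\n")
  invisible(x)
}

#' Photons required for a target refractive-index precision
#'
#' Inverts the error budget for the photon count: since the Poisson Fisher
#' information is linear in the photon flux at fixed SBR, the SMLM term
#' scales as `1/sqrt(N)` from a single reference evaluation, while the AFM
#' term is independent of N. Returns the smallest N with
#' `sqrt(delta_n_smlm(N)^2 + delta_n_afm^2) <= target_delta_n`.
#'
#' @param target_delta_n Desired total precision (> AFM floor).
#' @param system An [optical_system()].
#' @param sample A [layered_sample()].
#' @param sbr Signal-to-background ratio N / BG, held fixed while N scales.
#' @param afm An [afm_uncertainty()] or number (nm).
#' @param n_reference Photon count of the reference CRLB evaluation.
#' @param roi_size Optional ROI override.
#' @return Required photon count (ceiling), with the reference budget
#'   attached as attribute `budget`. If the target is at or below the AFM
#'   floor the value is `NA` with attribute `unattainable` naming the floor.
#' @examples
#' \donttest{
#' required_photons(1e-2, optical_system(), layered_sample(1.43, 50),
#'                  sbr = 100, afm = afm_uncertainty(1))
#' }
#' @export
required_photons <- function(target_delta_n, system, sample, sbr,
                             afm = afm_uncertainty(1), n_reference = 1e5,
                             roi_size = NULL) {
  stopifnot(target_delta_n > 0, sbr > 0)
  emitter <- emitter_state(axial_position = sample$thickness,
                           signal_photons = n_reference,
                           background_per_pixel = n_reference / sbr)
  d_afm <- as.numeric(delta_n_afm(system, sample, emitter, afm,
                                  roi_size = roi_size))
  if (target_delta_n <= d_afm) {
    return(structure(NA_real_, unattainable = TRUE, afm_floor = d_afm))
  }
  d_ref <- as.numeric(delta_n_smlm(system, sample, emitter,
                                   roi_size = roi_size))
  N <- ceiling(n_reference * d_ref^2 / (target_delta_n^2 - d_afm^2))
  structure(as.numeric(N),
            budget = total_delta_n(d_ref * sqrt(n_reference / N), d_afm))
}

#' Sweep the refractive-index error budget over thickness and SBR
#'
#' Evaluates the full precision budget on a grid of layer thicknesses and
#' signal-to-background ratios, with dyes at the layer top.
#'
#' @param system An [optical_system()].
#' @param H_nm Numeric vector of layer thicknesses (nm).
#' @param sbr Numeric vector of signal-to-background ratios.
#' @param N Signal photons per evaluation (default 1e5; results scale as
#'   `1/sqrt(N)` at fixed SBR).
#' @param n_layer Refractive index at which the bound is evaluated.
#' @param delta_z_afm AFM height error in nm (0 disables the AFM term).
#' @param track_focus If `TRUE` (default) the nominal focal plane is kept
#'   `system$defocus` nm above the layer top for every H (constant
#'   emitter-to-focus separation, the protocol used for thickness sweeps);
#'   if `FALSE` the focal plane stays fixed relative to the coverslip.
#' @param roi_size Optional ROI override.
#' @return A tibble of class `crlb_sweep` with columns `H_nm`, `sbr`, `N`,
#'   `delta_n_smlm`, `delta_n_afm`, `delta_n_total`.
#' @examples
#' \donttest{
#' crlb_sweep(optical_system(), H_nm = c(50, 100, 200), sbr = 100)
#' }
#' @export
crlb_sweep <- function(system, H_nm, sbr, N = 1e5, n_layer = 1.437,
                       delta_z_afm = 0, track_focus = TRUE,
                       roi_size = NULL) {
  grid <- tidyr::expand_grid(H_nm = H_nm, sbr = sbr)
  res <- purrr::pmap_dfr(grid, function(H_nm, sbr) {
    sys <- system
    if (track_focus) sys$defocus <- system$defocus + H_nm
    samp <- layered_sample(n_layer, H_nm)
    emit <- emitter_state(axial_position = H_nm, signal_photons = N,
                          background_per_pixel = N / sbr)
    ds <- as.numeric(delta_n_smlm(sys, samp, emit, roi_size = roi_size))
    da <- if (delta_z_afm > 0)
      as.numeric(delta_n_afm(sys, samp, emit, afm_uncertainty(delta_z_afm),
                             roi_size = roi_size)) else 0
    tibble(H_nm = H_nm, sbr = sbr, N = N, delta_n_smlm = ds,
           delta_n_afm = da, delta_n_total = sqrt(ds^2 + da^2))
  })
  class(res) <- c("crlb_sweep", class(res))
  res
}


#' Lateral-position Fisher information
#'
#' Scalar Fisher information about the emitter's lateral position (one
#' axis) for Poisson pixel counts; its inverse square root is the lateral
#' localization precision of a single image.
#'
#' @inheritParams fisher_information_n
#' @param step Finite-difference step in nm.
#' @return Nonnegative Fisher information (nm^-2).
#' @export
rimap_fisher_lateral <- function(system, sample, emitter, step = 2,
                                 roi_size = NULL) {
  .fi_eval(system, sample, emitter, step, roi_size, param = "x")
}
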