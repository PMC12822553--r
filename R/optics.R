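#' Describe the imaging system
#'
#' Bundles every instrument parameter that enters the image-formation model:
#' the objective and camera geometry, the refractive indices of the immersion
#' glass and the imaging buffer, the deliberate defocus, and residual pupil
#' aberrations expressed as Zernike coefficients.
#'
#' @param numerical_aperture Objective NA (dimensionless). Must be below
#'   `n_immersion`; values above `n_ambient` enable supercritical-angle
#'   collection, which carries most of the axial information.
#' @param emission_wavelength Peak emission wavelength in nm.
#' @param n_immersion Refractive index of the (matched) coverslip and
#'   immersion medium. Default 1.52.
#' @param n_ambient Refractive index of the imaging buffer above the sample
#'   (water/PBS, 1.33).
#' @param pixel_size_sample Camera pixel pitch back-projected into the sample
#'   plane, nm. Default 160 nm (16 um EMCCD pixel behind a 100x objective).
#' @param defocus Signed defocus in nm, entering as the glass-side pupil phase
#'   `-k0 * n_immersion * cos(theta_g) * defocus`; positive values displace
#'   the nominal focal plane away from the coverslip into the sample.
#' @param zernike_terms Named numeric vector of pupil-phase aberrations,
#'   names are Noll indices, values in radians at the pupil edge
#'   (unnormalized Zernike polynomials, `R_n^m(1) = 1`).
#' @param roi_size Odd side length, in pixels, of computed molecule images.
#' @param oversampling Sub-pixel sampling factor (integer >= 1) used when
#'   integrating the point spread function over camera pixels.
#'
#' @return An object of class `optical_system`.
#' @examples
#' sys <- optical_system()
#' sys
#' @export
optical_system <- function(numerical_aperture = 1.46,
                           emission_wavelength = 670,
                           n_immersion = 1.52,
                           n_ambient = 1.33,
                           pixel_size_sample = 160,
                           defocus = 500,
                           zernike_terms = NULL,
                           roi_size = 15,
                           oversampling = 6) {
  if (numerical_aperture >= n_immersion) {
    abort("invalid configuration: numerical_aperture must be < n_immersion",
          class = "rimap_config_error")
  }
  if (roi_size %% 2 != 1) {
    abort("invalid configuration: roi_size must be odd",
          class = "rimap_config_error")
  }
  if (oversampling < 1 || oversampling != round(oversampling)) {
    abort("invalid configuration: oversampling must be an integer >= 1",
          class = "rimap_config_error")
  }
  stopifnot(emission_wavelength > 0, pixel_size_sample > 0, n_ambient > 0)
  if (!is.null(zernike_terms)) {
    if (is.null(names(zernike_terms)) ||
        anyNA(suppressWarnings(as.integer(names(zernike_terms))))) {
      abort("zernike_terms must be named by integer Noll indices",
            class = "rimap_config_error")
    }
    zernike_terms <- zernike_terms[zernike_terms != 0]
    if (!length(zernike_terms)) zernike_terms <- NULL
  }
  structure(
    list(numerical_aperture = numerical_aperture,
         emission_wavelength = emission_wavelength,
         n_immersion = n_immersion,
         n_ambient = n_ambient,
         pixel_size_sample = pixel_size_sample,
         defocus = defocus,
         zernike_terms = zernike_terms,
         roi_size = as.integer(roi_size),
         oversampling = as.integer(oversampling)),
    class = "optical_system")
}

#' @export
print.optical_system <- function(x, ...) {
  cat("<optical_system> NA", x$numerical_aperture,
      " lambda", x$emission_wavelength, "nm",
      " n_g", x$n_immersion, " n_a", x$n_ambient,
      "\n  pixel", x$pixel_size_sample, "nm  defocus", x$defocus,
      "nm  roi", x$roi_size, "px  oversampling", x$oversampling, "\n")
  if (!is.null(x$zernike_terms)) {
    cat("  Zernike (Noll: rad):",
        paste(names(x$zernike_terms), round(x$zernike_terms, 3),
              sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Describe the sample layer
#'
#' The sample is modeled locally as a laterally infinite planar layer of
#' thickness `thickness` and refractive index `n_layer` sandwiched between
#' the coverslip and the imaging buffer. For a surface-labeled fibril the
#' layer thickness is the local fibril height and the dyes sit at the top
#' of the layer.
#'
#' @param n_layer Refractive index of the layer, in `[1, 2]`.
#' @param thickness Layer thickness H in nm (>= 0; 0 means no layer).
#' @return An object of class `layered_sample`.
#' @examples
#' layered_sample(1.437, 138)
#' @export
layered_sample <- function(n_layer = 1.43, thickness = 100) {
  if (thickness < 0) {
    abort("invalid input: thickness must be >= 0", class = "rimap_input_error")
  }
  if (n_layer < 1 || n_layer > 2) {
    abort("invalid input: n_layer must lie in [1, 2]",
          class = "rimap_input_error")
  }
  structure(list(n_layer = n_layer, thickness = thickness),
            class = "layered_sample")
}

#' @export
print.layered_sample <- function(x, ...) {
  cat("<layered_sample> n =", x$n_layer, " H =", x$thickness, "nm\n")
  invisible(x)
}

#' Describe a single emitter
#'
#' @param lateral_offset Length-2 numeric, nm offset of the emitter from the
#'   ROI center (x, y).
#' @param axial_position Height of the emitter above the coverslip surface in
#'   nm (z = 0 at the glass/sample interface). Dyes labeling the top surface
#'   of a layer of thickness H sit at `axial_position = H`.
#' @param signal_photons Expected number of detected signal photons N.
#' @param background_per_pixel Mean background photons per pixel BG. The
#'   signal-to-background ratio is `SBR = N / BG`.
#' @return An object of class `emitter_state`.
#' @examples
#' emitter_state(axial_position = 138, signal_photons = 1e5,
#'               background_per_pixel = 1e3)
#' @export
emitter_state <- function(lateral_offset = c(0, 0),
                          axial_position = 0,
                          signal_photons = 1000,
                          background_per_pixel = 10) {
  if (signal_photons < 0 || background_per_pixel < 0) {
    abort("invalid input: photon counts must be >= 0",
          class = "rimap_input_error")
  }
  stopifnot(length(lateral_offset) == 2, axial_position >= 0)
  structure(list(lateral_offset = as.numeric(lateral_offset),
                 axial_position = axial_position,
                 signal_photons = signal_photons,
                 background_per_pixel = background_per_pixel),
            class = "emitter_state")
}

#' @export
print.emitter_state <- function(x, ...) {
  sbr <- if (x$background_per_pixel > 0)
    x$signal_photons / x$background_per_pixel else Inf
  cat("<emitter_state> z =", x$axial_position, "nm  N =", x$signal_photons,
      " BG =", x$background_per_pixel, " (SBR", signif(sbr, 4), ")\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# pupil machinery (internal)

# Gauss-Legendre nodes/weights on [a, b] via Golub-Welsch
.gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  bv <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- bv
  J[cbind(i + 1, i)] <- bv
  e <- eigen(J, symmetric = TRUE)
  list(nodes = 0.5 * (b - a) * e$values + 0.5 * (a + b),
       weights = (b - a) * e$vectors[1, ]^2)
}

# Radial pupil quadrature + Bessel tables, cached per system geometry.
# krho runs over the collected cone, 0 .. k0*NA; the radial image grid r
# extends to r_max so that flux normalization captures the defocused tails.
.pupil_quadrature <- function(system, nk = 512, r_max = 9000, dr = 7.5) {
  key <- paste("pq", system$numerical_aperture, system$emission_wavelength,
               system$n_immersion, system$n_ambient, nk, r_max, dr, sep = "|")
  hit <- .rimap_cache[[key]]
  if (!is.null(hit)) return(hit)
  k0 <- 2 * pi / system$emission_wavelength
  gl <- .gauss_legendre(nk, 0, k0 * system$numerical_aperture)
  krho <- gl$nodes
  sg <- krho / (k0 * system$n_immersion)
  cg <- sqrt(1 - sg^2)
  sa <- krho / (k0 * system$n_ambient)
  ca <- sqrt(as.complex(1 - sa^2))      # +i sqrt(sa^2-1) beyond the critical angle
  r <- seq(0, r_max, by = dr)
  kr <- outer(r, krho)
  out <- list(k0 = k0, krho = krho, w = gl$weights, sg = sg, cg = cg,
              sa = sa, ca = ca, rho = krho / (k0 * system$numerical_aperture),
              r = r, dr = dr,
              J0 = besselJ(kr, 0), J1 = besselJ(kr, 1), J2 = besselJ(kr, 2))
  .rimap_cache[[key]] <- out
  out
}

# Fresnel transmission of the ambient(1)/layer(2)/glass(3) stack for the
# downward wave, including multiple reflections and the layer path
# (Airy formula); reduces exactly to the two-medium coefficient at H = 0.
.stack_transmission <- function(pq, n1, n2, n3, H) {
  c1 <- pq$ca
  s2 <- pq$krho / (pq$k0 * n2)
  c2 <- sqrt(as.complex(1 - s2^2))
  c3 <- pq$cg
  rs12 <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
  ts12 <- 2 * n1 * c1 / (n1 * c1 + n2 * c2)
  rs23 <- (n2 * c2 - n3 * c3) / (n2 * c2 + n3 * c3)
  ts23 <- 2 * n2 * c2 / (n2 * c2 + n3 * c3)
  rp12 <- (n2 * c1 - n1 * c2) / (n2 * c1 + n1 * c2)
  tp12 <- 2 * n1 * c1 / (n2 * c1 + n1 * c2)
  rp23 <- (n3 * c2 - n2 * c3) / (n3 * c2 + n2 * c3)
  tp23 <- 2 * n2 * c2 / (n3 * c2 + n2 * c3)
  eb <- exp(1i * pq$k0 * n2 * c2 * H)
  list(ts = ts12 * ts23 * eb / (1 + rs12 * rs23 * eb^2),
       tp = tp12 * tp23 * eb / (1 + rp12 * rp23 * eb^2))
}

# unnormalized radial Zernike polynomial R_n^0(rho) (R_n^0(1) = 1)
.zernike_radial <- function(n, rho) {
  stopifnot(n %% 2 == 0)
  s <- seq(0, n / 2)
  coefs <- (-1)^s * factorial(n - s) /
    (factorial(s) * factorial(n / 2 - s)^2)
  out <- 0
  for (i in seq_along(s)) out <- out + coefs[i] * rho^(n - 2 * s[i])
  out
}

# Noll index -> (n, m) with sign convention m<0 = sine term
.noll_to_nm <- function(j) {
  n <- 0
  while ((n + 1) * (n + 2) / 2 < j) n <- n + 1
  p <- j - n * (n + 1) / 2
  ms <- if (n %% 2 == 0) c(0, rep(seq(2, n, by = 2), each = 2)) else
    rep(seq(1, n, by = 2), each = 2)
  mabs <- ms[p]
  if (mabs == 0) return(c(n, 0))
  # Noll: odd j -> sine (m < 0), even j -> cosine (m > 0)
  c(n, if (j %% 2 == 0) mabs else -mabs)
}

.radial_zernike_phase <- function(system, rho) {
  zt <- system$zernike_terms
  if (is.null(zt)) return(0)
  phase <- 0
  for (j in names(zt)) {
    nm <- .noll_to_nm(as.integer(j))
    if (nm[2] != 0) next   # handled by the FFT path
    phase <- phase + zt[[j]] * .zernike_radial(nm[1], rho)
  }
  phase
}

.has_nonradial_zernike <- function(system) {
  zt <- system$zernike_terms
  if (is.null(zt)) return(FALSE)
  any(vapply(names(zt), function(j) .noll_to_nm(as.integer(j))[2] != 0,
             logical(1)))
}

# Radial intensity profile of the freely rotating dipole at height z above the
# coverslip, above a layer (n_layer, H), with glass-side defocus d.
# I(r) = |U0|^2 + |U2|^2 + 2 |U1|^2 with
#   U0 = int B (ts - tp ca) J0(kr) k dk      (in-plane dipoles)
#   U2 = int B (ts + tp ca) J2(kr) k dk
#   U1 = int B  tp sa       J1(kr) k dk      (axial dipole)
# B carries the sqrt(cos theta_g) aplanatic apodization, the propagation
# phase k0 n_a ca (z - H) - k0 n_g cg d, and radially symmetric Zernike terms.
# The returned profile integrates to unit flux: 2 pi int I(r) r dr = 1.
.psf_radial_profile <- function(system, n_layer, H, z, defocus = NULL,
                                r_max = NULL) {
  # A short radial grid (fit hot path) pairs with exact Parseval
  # normalization on the pupil side; the default long grid normalizes by
  # the real-space integral over its own field (the two scales differ by
  # the ~0.4% far-tail mass, absorbed into fitted photon counts).
  short <- !is.null(r_max)
  pq <- if (short) .pupil_quadrature(system, r_max = r_max) else
    .pupil_quadrature(system)
  d <- if (is.null(defocus)) system$defocus else defocus
  tt <- .stack_transmission(pq, system$n_ambient, n_layer, system$n_immersion, H)
  phase <- pq$k0 * system$n_ambient * pq$ca * (z - H) -
    pq$k0 * system$n_immersion * pq$cg * d +
    .radial_zernike_phase(system, pq$rho)
  B <- sqrt(pq$cg) * exp(1i * phase) * pq$krho * pq$w
  U0 <- pq$J0 %*% (B * (tt$ts - tt$tp * pq$ca))
  U2 <- pq$J2 %*% (B * (tt$ts + tt$tp * pq$ca))
  U1 <- pq$J1 %*% (B * (tt$tp * pq$sa))
  I <- Mod(U0)^2 + Mod(U2)^2 + 2 * Mod(U1)^2
  I <- as.numeric(I)
  S <- if (short) {
    # Hankel-Parseval: int |U_m|^2 r dr = int |a_m|^2 k dk per order
    2 * pi * sum((Mod(tt$ts - tt$tp * pq$ca)^2 +
                    Mod(tt$ts + tt$tp * pq$ca)^2 +
                    2 * Mod(tt$tp * pq$sa)^2) * pq$cg * pq$krho * pq$w)
  } else {
    2 * pi * pq$dr * sum(I * pq$r)   # trapezoid on a uniform grid
  }
  list(r = pq$r, I = I / S)
}

# Fine-grid coordinates of an ROI (cached): offsets of oversampled sub-pixel
# sample points from the ROI center, plus the binning index.
.roi_fine_grid <- function(roi_size, px, os) {
  key <- paste("grid", roi_size, px, os, sep = "|")
  hit <- .rimap_cache[[key]]
  if (!is.null(hit)) return(hit)
  half <- (roi_size - 1) / 2
  centers <- seq(-half, half) * px
  sub <- (seq_len(os) - (os + 1) / 2) * (px / os)
  fine <- as.vector(t(outer(centers, sub, "+")))   # ordered by pixel then sub
  n <- roi_size * os
  xs <- rep(fine, times = n)
  ys <- rep(fine, each = n)
  pix_i <- rep(rep(seq_len(roi_size), each = os), times = n)
  pix_j <- rep(rep(seq_len(roi_size), each = os), each = n)
  bin <- (pix_j - 1L) * roi_size + pix_i
  out <- list(xs = xs, ys = ys, bin = bin, n_sub = os^2)
  .rimap_cache[[key]] <- out
  out
}

# Render expected pixel values (photons) from a radial profile.
# Pixel value = mean over os^2 sub-samples of I(r) * pixel area * N  (+ BG).
.render_from_profile <- function(prof, system, x0 = 0, y0 = 0,
                                 N = 1, BG = 0, roi_size = NULL) {
  roi <- if (is.null(roi_size)) system$roi_size else roi_size
  g <- .roi_fine_grid(roi, system$pixel_size_sample, system$oversampling)
  r <- sqrt((g$xs - x0)^2 + (g$ys - y0)^2)
  # linear interpolation on the uniform radial grid (fit hot path)
  dr <- prof$r[2] - prof$r[1]
  nmax <- length(prof$r)
  fi <- pmin(r / dr, nmax - 1.000001)
  i0 <- floor(fi)
  w <- fi - i0
  Iv <- prof$I[i0 + 1] * (1 - w) + prof$I[i0 + 2] * w
  v <- rowsum(Iv, g$bin, reorder = TRUE) / g$n_sub
  matrix(v, roi, roi) * system$pixel_size_sample^2 * N + BG
}

# ---------------------------------------------------------------------------
# FFT (Cartesian pupil) path: needed for non-radially-symmetric aberrations,
# and used as an internal cross-check of the radial path.
.psf_image_fft <- function(system, n_layer, H, z, x0 = 0, y0 = 0,
                           defocus = NULL, roi_size = NULL) {
  roi <- if (is.null(roi_size)) system$roi_size else roi_size
  os <- system$oversampling
  if (os %% 2 == 0) os <- os + 1   # FFT grid needs a center sample
  d <- if (is.null(defocus)) system$defocus else defocus
  fine_px <- system$pixel_size_sample / os
  M <- 2^ceiling(log2(max(4 * roi * os, 256)))
  k0 <- 2 * pi / system$emission_wavelength
  dk <- 2 * pi / (M * fine_px)
  kx <- (seq_len(M) - 1 - M %/% 2) * dk
  KX <- matrix(kx, M, M)
  KY <- t(KX)
  KR <- sqrt(KX^2 + KY^2)
  inside <- KR <= k0 * system$numerical_aperture
  krho <- KR[inside]
  phi <- atan2(KY[inside], KX[inside])
  n_g <- system$n_immersion
  n_a <- system$n_ambient
  sg <- krho / (k0 * n_g); cg <- sqrt(pmax(1 - sg^2, 0))
  sa <- krho / (k0 * n_a); ca <- sqrt(as.complex(1 - sa^2))
  pq <- list(k0 = k0, krho = krho, ca = ca, cg = cg)
  tt <- .stack_transmission(pq, n_a, n_layer, n_g, H)
  phase <- k0 * n_a * ca * (z - H) - k0 * n_g * cg * d +
    krho * cos(phi) * x0 + krho * sin(phi) * y0
  zt <- system$zernike_terms
  if (!is.null(zt)) {
    rho <- krho / (k0 * system$numerical_aperture)
    for (j in names(zt)) {
      nm <- .noll_to_nm(as.integer(j))
      rad <- .zernike_radial_m(nm[1], abs(nm[2]), rho)
      azi <- if (nm[2] == 0) 1 else if (nm[2] > 0) cos(nm[2] * phi) else
        sin(-nm[2] * phi)
      phase <- phase + zt[[j]] * rad * azi
    }
  }
  B <- sqrt(cg) * exp(1i * phase)
  # pupil fields: p-component along rho-hat, s-component along s-hat
  # dipole x: As = -sin(phi), Ap = -ca cos(phi)
  # dipole y: As =  cos(phi), Ap = -ca sin(phi)
  # dipole z: As =  0,        Ap = -sa
  cph <- cos(phi); sph <- sin(phi)
  fields <- list(
    list(As = -sph, Ap = -ca * cph),
    list(As = cph,  Ap = -ca * sph),
    list(As = 0,    Ap = -sa + 0i))
  acc <- matrix(0, M, M)
  for (f in fields) {
    Ep <- tt$tp * f$Ap * B
    Es <- tt$ts * f$As * B
    Ex <- matrix(0i, M, M); Ey <- matrix(0i, M, M)
    Ex[inside] <- Ep * cph - Es * sph
    Ey[inside] <- Ep * sph + Es * cph
    ex <- stats::fft(Ex); ey <- stats::fft(Ey)
    acc <- acc + Mod(ex)^2 + Mod(ey)^2
  }
  # reorder FFT output so the ROI center sits mid-grid
  shift <- function(m) {
    h <- M %/% 2
    m[c((h + 1):M, 1:h), c((h + 1):M, 1:h)]
  }
  acc <- shift(acc)
  S <- sum(acc)                         # flux over the full computed field
  # bin os x os sub-pixels around the center into roi x roi camera pixels
  c0 <- M %/% 2 + 1
  half <- (roi * os) %/% 2
  idx <- (c0 - half):(c0 + half - 1 + (roi * os) %% 2)
  fine <- acc[idx, idx]
  binned <- matrix(0, roi, roi)
  for (i in seq_len(roi)) {
    rows <- (i - 1) * os + seq_len(os)
    sub <- fine[rows, , drop = FALSE]
    binned[i, ] <- vapply(seq_len(roi), function(j)
      sum(sub[, (j - 1) * os + seq_len(os)]), numeric(1))
  }
  binned / S
}

# full (n, m) radial Zernike
.zernike_radial_m <- function(n, m, rho) {
  s <- seq(0, (n - m) / 2)
  coefs <- (-1)^s * factorial(n - s) /
    (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
  out <- 0
  for (i in seq_along(s)) out <- out + coefs[i] * rho^(n - 2 * s[i])
  out
}

# ---------------------------------------------------------------------------

#' Compute the expected image of a single molecule
#'
#' Forms the expected photon counts on the camera ROI for a freely rotating
#' dipole emitter above a coverslip carrying an intermediate sample layer.
#' The model propagates each plane-wave component of the three orthogonal
#' emission dipoles through the buffer/layer/glass stack with Fresnel
#' transmission for s and p polarization (supercritical angles included),
#' applies the defocus and aberration pupil phases, integrates the intensity
#' over each camera pixel by oversampling, normalizes the background-free
#' image so the flux over a large field equals `signal_photons`, and adds
#' the uniform background.
#'
#' @param system An [optical_system()].
#' @param sample A [layered_sample()].
#' @param emitter An [emitter_state()]. For dyes labeling the top surface of
#'   the layer use `axial_position = sample$thickness`.
#' @param roi_size Optional ROI override (odd, pixels).
#'
#' @return A `molecule_image`: the `roi_size x roi_size` matrix of expected
#'   photons with the generating configuration attached as attributes.
#' @examples
#' sys <- optical_system(oversampling = 2)
#' img <- compute_molecule_image(sys, layered_sample(1.48, 100),
#'                               emitter_state(axial_position = 100,
#'                                             signal_photons = 5000,
#'                                             background_per_pixel = 10))
#' sum(img - 10) / 5000  # fraction of the flux captured by the ROI
#' @export
compute_molecule_image <- function(system, sample, emitter, roi_size = NULL) {
  stopifnot(inherits(system, "optical_system"),
            inherits(sample, "layered_sample"),
            inherits(emitter, "emitter_state"))
  roi <- if (is.null(roi_size)) system$roi_size else as.integer(roi_size)
  if (roi %% 2 != 1) {
    abort("invalid configuration: roi_size must be odd",
          class = "rimap_config_error")
  }
  N <- emitter$signal_photons
  BG <- emitter$background_per_pixel
  if (N == 0) {
    img <- matrix(BG, roi, roi)
  } else if (.has_nonradial_zernike(system)) {
    img <- .psf_image_fft(system, sample$n_layer, sample$thickness,
                          emitter$axial_position,
                          x0 = emitter$lateral_offset[1],
                          y0 = emitter$lateral_offset[2],
                          roi_size = roi) * N + BG
  } else {
    prof <- .psf_radial_profile(system, sample$n_layer, sample$thickness,
                                emitter$axial_position)
    img <- .render_from_profile(prof, system,
                                x0 = emitter$lateral_offset[1],
                                y0 = emitter$lateral_offset[2],
                                N = N, BG = BG, roi_size = roi)
  }
  structure(img, class = c("molecule_image", "matrix"),
            system = system, sample = sample, emitter = emitter)
}

#' @export
print.molecule_image <- function(x, ...) {
  cat("<molecule_image>", nrow(x), "x", ncol(x),
      "px, total", signif(sum(x), 6), "photons\n")
  invisible(x)
}

#' Radial second moment of an image
#'
#' Background-corrected second moment `sum(I * r^2) / sum(I)` about the
#' photon-weighted centroid, in nm^2. Used to quantify point-spread-function
#' broadening.
#'
#' @param img Matrix of pixel values (a `molecule_image` or plain matrix).
#' @param pixel_size Pixel pitch in nm.
#' @param background Constant background to subtract before weighting
#'   (default 0).
#' @return Second moment in nm^2.
#' @export
psf_second_moment <- function(img, pixel_size = 160, background = 0) {
  if (inherits(img, "molecule_image")) {
    pixel_size <- attr(img, "system")$pixel_size_sample
    background <- attr(img, "emitter")$background_per_pixel
  }
  w <- pmax(unclass(img) - background, 0)
  n <- nrow(w)
  cc <- (seq_len(n) - (n + 1) / 2) * pixel_size
  X <- matrix(cc, n, n)
  Y <- t(X)
  cx <- sum(w * X) / sum(w)
  cy <- sum(w * Y) / sum(w)
  sum(w * ((X - cx)^2 + (Y - cy)^2)) / sum(w)
}

#' Write an expected molecule image as 32-bit float TIFF
#'
#' @param img A `molecule_image` or numeric matrix (photons).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_molecule_tiff <- function(img, path) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m / max(max(m), 1e-300), path,
                  bits.per.sample = 32, reduce = FALSE)
  # writeTIFF stores [0,1]; keep physical scale in a sidecar tag-free way:
  # rescale is undone by the reader via the stored maximum.
  invisible(path)
}
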