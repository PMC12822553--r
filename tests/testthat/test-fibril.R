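# drift -------------------------------------------------------------------

test_that("static fiducials leave localizations unchanged", {
  locs <- tibble::tibble(frame = 1:50, x_nm = runif(50, 0, 5000),
                         y_nm = runif(50, 0, 5000), z_nm = 0)
  fid <- tibble::tibble(frame = 1:50, x_nm = 1000, y_nm = 2000)
  out <- correct_drift(locs, fid)
  expect_equal(out$x_nm, locs$x_nm)
  expect_equal(out$y_nm, locs$y_nm)
  expect_lt(attr(out, "residual_rms"), 1e-9)
})

test_that("linear drift is removed to a few percent RMS", {
  nf <- 2000
  drift_x <- 0.1 * (0:(nf - 1))        # 0.1 nm / frame
  set.seed(21)
  fid <- tibble::tibble(frame = 1:nf, x_nm = 5000 + drift_x,
                        y_nm = 3000)
  locs <- tibble::tibble(frame = 1:nf, x_nm = 1000 + drift_x, y_nm = 1000,
                         z_nm = 0)
  out <- correct_drift(locs, fid)
  rms <- sqrt(mean((out$x_nm - 1000)^2))
  expect_lt(rms, 0.05 * sqrt(mean(drift_x^2)))
})

test_that("two noisy fiducials beat one", {
  nf <- 500
  set.seed(22)
  drift_x <- cumsum(rnorm(nf, 0, 0.5))
  mk_fid <- function(id, x0) tibble::tibble(
    fid_id = id, frame = 1:nf, x_nm = x0 + drift_x + rnorm(nf, 0, 10),
    y_nm = 0)
  locs <- tibble::tibble(frame = 1:nf, x_nm = 100 + drift_x, y_nm = 0,
                         z_nm = 0)
  r1 <- sqrt(mean((correct_drift(locs, mk_fid(1, 5e3))$x_nm - 100)^2))
  r2 <- sqrt(mean((correct_drift(
    locs, dplyr::bind_rows(mk_fid(1, 5e3), mk_fid(2, 8e3)))$x_nm - 100)^2))
  expect_lt(r2, r1)
})

test_that("frames outside the fiducial span are an error naming the gap", {
  locs <- tibble::tibble(frame = c(1, 200), x_nm = 0, y_nm = 0, z_nm = 0)
  fid <- tibble::tibble(frame = 1:100, x_nm = 0, y_nm = 0)
  expect_error(correct_drift(locs, fid), "200")
})

# reference plane ----------------------------------------------------------

test_that("defocus and tilt are recovered from glass-bound molecules", {
  sys <- fast_system(defocus = 500)
  true_defocus <- 520
  render_sys <- fast_system(defocus = true_defocus)
  glass <- layered_sample(1.33, 0)
  set.seed(23)
  n_gl <- 40
  xs <- runif(n_gl, 0, 7000); ys <- runif(n_gl, 0, 7000)
  tilt <- 1e-3                     # 1 nm per um in x
  rois <- lapply(seq_len(n_gl), function(k) {
    z_k <- tilt * xs[k] - 3        # tilted coverslip
    img <- compute_molecule_image(render_sys, glass,
                                  emitter_state(c(0, 0), max(z_k, 0),
                                                2e4, 20))
    structure(list(counts = matrix(rpois(225, unclass(img)), 15, 15),
                   center_px = round(c(xs[k], ys[k]) / 160),
                   frame = k), class = "molecule_roi")
  })
  init <- tibble::tibble(x_nm = round(xs / 160) * 160,
                         y_nm = round(ys / 160) * 160)
  plane <- fit_reference_plane_and_defocus(rois, sys,
                                           scan_range = c(400, 650),
                                           init_positions = init)
  expect_lt(abs(plane$fitted_defocus - true_defocus), 8)
  expect_lt(abs(plane$slope_x - tilt), 3e-4)
  corrected <- apply_reference_plane(plane$glass_localizations, plane)
  expect_lt(abs(mean(corrected$z_nm)), 1)
})

test_that("too few glass localizations are rejected", {
  expect_error(fit_reference_plane_and_defocus(list(), fast_system()),
               class = "rimap_input_error")
})

# axis and cross-section geometry -----------------------------------------

test_that("a straight fibril gives the identity transform", {
  set.seed(24)
  locs <- tibble::tibble(x_nm = runif(500, 0, 6000),
                         y_nm = 2000, z_nm = 50)
  axis <- fit_fibril_axis(locs)
  cs <- transform_to_cross_section(locs, axis)
  expect_lt(max(abs(cs$X_nm)), 1)
  expect_lt(max(abs(cs$Z_nm - 50)), 1e-9)
  # s is arclength from the curve start: monotone in x
  expect_true(all(diff(cs$s_nm[order(locs$x_nm)]) > 0))
})

test_that("a circular-arc axis is recovered within 5 nm RMS", {
  R <- 5000
  th <- seq(-0.5, 0.5, length.out = 800)
  pts <- tibble::tibble(x_nm = 6000 + R * sin(th),
                        y_nm = 2000 + R * (1 - cos(th)))
  axis <- fit_fibril_axis(pts, df = 6, bin_nm = 0)
  d <- sqrt((axis$dense$x_nm - 6000)^2 + (axis$dense$y_nm - 2000 - R)^2)
  expect_lt(sqrt(mean((d - R)^2)), 5)
  # re-running gives the identical curve
  axis2 <- fit_fibril_axis(pts, df = 6, bin_nm = 0)
  expect_identical(axis$dense, axis2$dense)
})

test_that("nearest-point projection matches the analytic circle distance", {
  R <- 5000
  th <- seq(-0.5, 0.5, length.out = 800)
  pts <- tibble::tibble(x_nm = 6000 + R * sin(th),
                        y_nm = 2000 + R * (1 - cos(th)))
  axis <- fit_fibril_axis(pts, df = 6, bin_nm = 0)
  # a point 80 nm outside the arc at its middle
  p <- tibble::tibble(x_nm = 6000, y_nm = 2000 - 80, z_nm = 10)
  cs <- transform_to_cross_section(p, axis)
  expect_lt(abs(abs(cs$X_nm) - 80), 1.5)
  expect_false(cs$boundary)
})

test_that("reflection across the axis flips X and preserves s and Z", {
  set.seed(25)
  locs <- tibble::tibble(x_nm = runif(300, 500, 5500), y_nm = 2000,
                         z_nm = 0)
  axis <- fit_fibril_axis(locs)
  p_up <- tibble::tibble(x_nm = 3000, y_nm = 2000 + 60, z_nm = 5)
  p_dn <- tibble::tibble(x_nm = 3000, y_nm = 2000 - 60, z_nm = 5)
  cs_up <- transform_to_cross_section(p_up, axis)
  cs_dn <- transform_to_cross_section(p_dn, axis)
  expect_equal(cs_up$X_nm, -cs_dn$X_nm, tolerance = 1e-6)
  expect_equal(cs_up$s_nm, cs_dn$s_nm, tolerance = 1e-6)
  expect_equal(cs_up$Z_nm, cs_dn$Z_nm)
})

test_that("cross-section coordinates round trip to the lab frame", {
  set.seed(26)
  locs <- tibble::tibble(x_nm = runif(400, 0, 6000), y_nm = 2000, z_nm = 0)
  axis <- fit_fibril_axis(locs)
  pts <- tibble::tibble(x_nm = c(1500, 3000, 4500),
                        y_nm = c(2080, 1930, 2005), z_nm = 0)
  cs <- transform_to_cross_section(pts, axis)
  back <- cross_section_to_lab(axis, cs$s_nm, cs$X_nm)
  expect_lt(max(abs(back$x_nm - pts$x_nm)), 1)
  expect_lt(max(abs(back$y_nm - pts$y_nm)), 1)
})

test_that("degenerate point clouds are rejected", {
  blob <- tibble::tibble(x_nm = rnorm(100, 0, 20), y_nm = rnorm(100, 0, 20))
  expect_error(fit_fibril_axis(blob), class = "rimap_input_error")
})

# outlier filtering --------------------------------------------------------

test_that("DBSCAN removes dispersed outliers but keeps the half-ring", {
  set.seed(27)
  ring <- half_cylinder_cs(800, R = 69, z_noise = 5)
  out_n <- 40
  outliers <- tibble::tibble(
    s_nm = runif(out_n, 0, 4000),
    X_nm = runif(out_n, -3 * 69, 3 * 69),
    Z_nm = runif(out_n, 120, 400))
  mixed <- dplyr::bind_rows(ring, outliers)
  kept <- filter_outliers(mixed, eps = 30, min_samples = 10)
  is_kept_outlier <- nrow(dplyr::semi_join(kept, outliers,
                                           by = c("X_nm", "Z_nm")))
  expect_lte(is_kept_outlier, 0.1 * out_n)
  inliers_lost <- nrow(ring) - (nrow(kept) - is_kept_outlier)
  expect_lte(inliers_lost, 0.02 * nrow(ring))
})

test_that("a clean cluster passes through nearly untouched", {
  cs <- half_cylinder_cs(600, R = 69, z_noise = 3, seed = 28)
  kept <- filter_outliers(cs)
  expect_lte(attr(kept, "removed_fraction"), 0.01)
})

test_that("all-noise input is an error suggesting parameter revision", {
  sparse <- tibble::tibble(X_nm = seq(0, 1e5, by = 1000),
                           Z_nm = seq(0, 1e5, by = 1000))
  expect_error(filter_outliers(sparse, eps = 30, min_samples = 10),
               "revise")
})

# height estimation --------------------------------------------------------

test_that("a constant height field returns that height", {
  cs <- tibble::tibble(X_nm = seq(-100, 100, length.out = 200), Z_nm = 80)
  h <- estimate_height(cs, window_nlocs = 40)
  expect_equal(h$H, 80)
})

test_that("the crest of a labeled half-cylinder is recovered", {
  cs <- half_cylinder_cs(1000, R = 69, z_noise = 0, seed = 29)
  h0 <- estimate_height(cs, window_nlocs = 40)
  expect_lt(abs(h0$H - 69), 2)
  csn <- half_cylinder_cs(1000, R = 69, z_noise = 5, seed = 30)
  hn <- estimate_height(csn, window_nlocs = 40)
  expect_lt(abs(hn$H - 69), 2)
})

test_that("the debris offset shifts the height additively", {
  cs <- half_cylinder_cs(500, R = 69, seed = 31)
  h0 <- estimate_height(cs, window_nlocs = 40)
  h1 <- estimate_height(cs, window_nlocs = 40, debris_offset = 3.5)
  expect_equal(h1$H - h0$H, 3.5)
})

test_that("too few localizations for a window is an error", {
  cs <- tibble::tibble(X_nm = 1:5, Z_nm = 1)
  expect_error(estimate_height(cs, window_nlocs = 40),
               class = "rimap_input_error")
})

# resampling error ---------------------------------------------------------

test_that("identical localizations have zero height error", {
  cs <- tibble::tibble(X_nm = rep(0, 100), Z_nm = 50)
  expect_equal(resample_height_error(cs, window_nlocs = 20,
                                     n_resamples = 200), 0)
})

test_that("half-sample resampling matches the estimator's true sampling error", {
  # noise-dominated regime: Gaussian height noise on a flat surface patch
  n <- 1500
  gen <- function(seed) {
    set.seed(seed)
    tibble::tibble(X_nm = runif(n, -100, 100), Z_nm = 80 + rnorm(n, 0, 5))
  }
  est <- resample_height_error(gen(1), window_nlocs = 40,
                               n_resamples = 600, seed = 99)
  # brute-force sampling distribution of the full estimator
  oracle <- sd(vapply(1:600, function(s) {
    cs <- gen(1000 + s)
    rimap:::.height_core(cs$X_nm, cs$Z_nm, 40)$H
  }, numeric(1)))
  expect_lt(abs(est - oracle) / oracle, 0.25)
})

test_that("the resampling estimate is stable in the number of resamples", {
  cs <- half_cylinder_cs(800, R = 69, z_noise = 5, seed = 33)
  e1 <- resample_height_error(cs, 40, n_resamples = 600, seed = 1)
  e2 <- resample_height_error(cs, 40, n_resamples = 1200, seed = 1)
  expect_lt(abs(e1 - e2) / e1, 0.10)
})

# refractive-index intersection -------------------------------------------

test_that("an exact linear height grid intersects at the true index", {
  heights <- tibble::tibble(n_assumed = c(1.38, 1.43, 1.48),
                            H = 100 + 210 * (c(1.38, 1.43, 1.48) - 1.43))
  ri <- estimate_refractive_index(heights, list(H = 100, sigma_H = NA_real_))
  expect_equal(ri$n, 1.43, tolerance = 1e-9)
  expect_gt(ri$slope, 0)
})

test_that("a non-positive slope violates the model and errors", {
  heights <- tibble::tibble(n_assumed = c(1.38, 1.43, 1.48),
                            H = c(100, 90, 80))
  expect_error(estimate_refractive_index(heights, list(H = 90, sigma_H = NA)),
               class = "rimap_model_error")
})

test_that("intersections outside the plausible range are flagged", {
  heights <- tibble::tibble(n_assumed = c(1.38, 1.43, 1.48),
                            H = 100 + 210 * (c(1.38, 1.43, 1.48) - 1.43))
  expect_warning(
    ri <- estimate_refractive_index(heights, list(H = 180, sigma_H = NA)),
    "outside")
  expect_true(ri$outside_range)
})

# error propagation --------------------------------------------------------

test_that("zero height errors propagate to zero index error", {
  heights <- tibble::tibble(n_assumed = c(1.38, 1.43, 1.48),
                            H = c(90, 100, 110), sigma_H = 0)
  expect_equal(propagate_ri_error(heights, list(H = 100, sigma_H = 0),
                                  n_draws = 500), 0)
})

test_that("Monte Carlo propagation matches the closed form", {
  b <- 210; m <- 5
  grid <- seq(1.38, 1.48, length.out = m)
  sH <- 0.6; sA <- 0.5
  heights <- tibble::tibble(n_assumed = grid,
                            H = 100 + b * (grid - 1.43), sigma_H = sH)
  got <- propagate_ri_error(heights, list(H = 100, sigma_H = sA),
                            n_draws = 20000, seed = 5)
  expected <- sqrt(sH^2 / m + sA^2) / b
  expect_lt(abs(got - expected) / expected, 0.10)
  # doubling all errors doubles the propagated error
  heights2 <- dplyr::mutate(heights, sigma_H = 2 * sH)
  got2 <- propagate_ri_error(heights2, list(H = 100, sigma_H = 2 * sA),
                             n_draws = 20000, seed = 5)
  expect_lt(abs(got2 - 2 * got) / (2 * got), 0.05)
})

test_that("a common-mode reference error adds a line-shift term", {
  b <- 210; m <- 3
  grid <- c(1.38, 1.43, 1.48)
  heights <- tibble::tibble(n_assumed = grid, H = 100 + b * (grid - 1.43),
                            sigma_H = 0.01)
  sc <- 1.5
  got <- propagate_ri_error(heights, list(H = 100, sigma_H = 0.01),
                            n_draws = 20000, seed = 6, sigma_common = sc)
  expect_lt(abs(got - sc / b) / (sc / b), 0.10)
})

# swelling -----------------------------------------------------------------

test_that("the mixing model inverts exactly", {
  r0 <- swelling_and_dry_index(5000, 5000, 1.5)
  expect_equal(r0$delta_A, 0)
  expect_equal(r0$n_dry, 1.5)
  # worked numbers: n_dry = 1.53 at delta_A = 1 gives n_collagen = 1.43
  fwd <- (1.53 + 1 * 1.33) / (1 + 1)
  expect_equal(fwd, 1.43)
  inv <- swelling_and_dry_index(5000, 10000, fwd)
  expect_equal(inv$n_dry, 1.53, tolerance = 1e-12)
  # shrinkage is allowed but flagged
  expect_true(swelling_and_dry_index(1e4, 9e3, 1.43)$shrinkage)
})

# cross-sectional area -----------------------------------------------------

test_that("numerical integration reproduces analytic areas", {
  r <- 100
  X <- (seq(-4, 3) + 0.5) * 39       # pixel-center sampling, 39 nm pitch
  semi <- tibble::tibble(X_nm = X,
                         height = sqrt(pmax(r^2 - X^2, 0)))
  expect_lt(abs(cross_sectional_area(semi) - pi * r^2 / 2) / (pi * r^2 / 2),
            0.01)
  flat <- tibble::tibble(X_nm = X, height = 0)
  expect_equal(cross_sectional_area(flat), 0)
  rect <- tibble::tibble(X_nm = c(0, 200), height = 100)
  expect_equal(cross_sectional_area(rect), 2e4)
  bad <- tibble::tibble(X_nm = c(0, 50, 20), height = 1)
  expect_error(cross_sectional_area(bad), class = "rimap_input_error")
})

# along-fibril mapping -----------------------------------------------------

afm_flat_profile <- function(L = 5000, H = 100, sigma = 0.3) {
  tibble::tibble(s_nm = seq(0, L, by = 250), H = H, sigma_H = sigma)
}

test_that("a homogeneous fibril maps to a constant refractive index", {
  cs <- cs_by_n_mechanism(n_locs = 1200, seed = 41)
  mp <- map_ri_along_fibril(cs, afm_flat_profile(), window_nlocs = 100,
                            overlap_fraction = 0.8, n_resamples = 40,
                            n_draws = 1000, seed = 7)
  ok <- mp[!mp$skipped, ]
  expect_gt(nrow(ok), 5)
  expect_lt(max(abs(ok$n - 1.43)), 4 * max(ok$sigma_n_exp))
  # bookkeeping: floor((total - window) / step) + 1 windows
  step <- max(1, round(100 * 0.2))
  expect_equal(nrow(mp), floor((1200 - 100) / step) + 1)
})

test_that("a refractive-index step is localized within two window extents", {
  step_fun <- function(s) ifelse(s < 2000, 1.40, 1.45)
  cs <- cs_by_n_mechanism(n_locs = 2000, n_true_fun = step_fun,
                          z_noise = 2, seed = 42)
  mp <- map_ri_along_fibril(cs, afm_flat_profile(), window_nlocs = 100,
                            overlap_fraction = 0.8, n_resamples = 40,
                            n_draws = 500, seed = 8)
  ok <- mp[!mp$skipped, ]
  lo <- ok$s_nm < 2000 - 2 * ok$window_nm
  hi <- ok$s_nm > 2000 + 2 * ok$window_nm
  # away from the step both plateaus are internally homogeneous and their
  # separation matches the injected 0.05 step (the estimator's common crest
  # bias cancels in the difference)
  expect_lt(max(abs(ok$n[lo] - mean(ok$n[lo]))), 0.02)
  expect_lt(max(abs(ok$n[hi] - mean(ok$n[hi]))), 0.02)
  expect_lt(abs((mean(ok$n[hi]) - mean(ok$n[lo])) - 0.05), 0.015)
})

test_that("variance decomposition recovers injected sample variance", {
  # short-correlation refractive-index field: iid per 250 nm block
  set.seed(43)
  blocks <- rnorm(21, 1.45, 0.03)
  field <- function(s) blocks[pmin(floor(s / 250) + 1, 21)]
  cs <- cs_by_n_mechanism(n_locs = 2000, n_true_fun = field,
                          z_noise = 2, seed = 44)
  maps <- lapply(c(100, 200, 400), function(w) {
    map_ri_along_fibril(cs, afm_flat_profile(), window_nlocs = w,
                        overlap_fraction = 0.7, n_resamples = 40,
                        n_draws = 500, seed = 9)
  })
  vd <- variance_decomposition(maps)
  expect_equal(nrow(vd), 3)
  # injected variance at the smallest window: variance of the window-mean
  # of the block field (blocks of ~250 nm, window ~ one to two blocks)
  w_nm <- vd$mean_distance_nm[1]
  n_eff <- max(1, w_nm / 250)
  injected <- 0.03^2 / n_eff
  expect_lt(abs(vd$var_collagen[1] - injected) / injected, 0.5)
  # averaging: variance falls with window size
  expect_true(vd$var_collagen[3] <= vd$var_collagen[1])
})

test_that("noise-free homogeneous fibrils decompose to zero sample variance", {
  cs <- cs_by_n_mechanism(n_locs = 1000, z_noise = 0, seed = 45)
  mp <- map_ri_along_fibril(cs, afm_flat_profile(sigma = 1e-6),
                            window_nlocs = 100, overlap_fraction = 0.7,
                            n_resamples = 30, n_draws = 200, seed = 10)
  vd <- variance_decomposition(list(mp))
  expect_lt(vd$var_collagen, 1e-6)
})
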