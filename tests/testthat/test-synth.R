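test_that("phantom emitter counts follow the Poisson point process", {
  phantom <- fibril_phantom(length = 5000, radius_wet = 100,
                            radius_dry = 60, label_density = 400,
                            glass_density = 2)
  em <- generate_phantom(phantom, seed = 61)
  fib <- em[!em$on_glass, ]
  lambda <- 400 * pi * 100 * 5000 / 1e6
  expect_lt(abs(nrow(fib) - lambda), 3 * sqrt(lambda))
  expect_true(all(fib$z_nm >= 0 & fib$z_nm <= 100 + 1e-9))
  expect_true(all(abs(fib$X_nm) <= 100 + 1e-9))
  expect_true(all(em$z_nm[em$on_glass] == 0))
  # constant refractive-index profile is stored as constant
  expect_equal(unique(fib$n_true), 1.43)
})

test_that("a zero-radius phantom places everything on the glass plane", {
  phantom <- fibril_phantom(radius_wet = 0, radius_dry = 1e-6,
                            glass_density = 2)
  em <- generate_phantom(phantom, seed = 62)
  expect_true(all(em$z_nm == 0))
})

test_that("reproducibility: same seed, same phantom", {
  phantom <- fibril_phantom()
  expect_identical(generate_phantom(phantom, seed = 7),
                   generate_phantom(phantom, seed = 7))
})

test_that("an emitter-free stack is pure Poisson background", {
  phantom <- fibril_phantom(label_density = 0, glass_density = 0,
                            field_nm = c(32 * 160, 32 * 160))
  em <- generate_phantom(phantom, seed = 63)
  acq <- acquisition_model(frames = 30, frame_px = c(32, 32),
                           background = 12,
                           fiducials = tibble::tibble(x_nm = numeric(),
                                                      y_nm = numeric(),
                                                      photons = numeric()),
                           seed = 64)
  ren <- render_smlm_stack(em, acq, fast_system(), phantom)
  counts <- unlist(ren$stack)
  expect_lt(abs(mean(counts) - 12) / 12, 0.02)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.05)
})

test_that("photons per burst match the configured mean", {
  phantom <- fibril_phantom(length = 2000, radius_wet = 60, radius_dry = 40,
                            label_density = 1500, glass_density = 0,
                            field_nm = c(32 * 160, 32 * 160))
  em <- generate_phantom(phantom, seed = 65)
  acq <- acquisition_model(frames = 120, frame_px = c(32, 32), p_on = 0.15,
                           mean_photons = 1000, seed = 66,
                           fiducials = tibble::tibble(x_nm = numeric(),
                                                      y_nm = numeric(),
                                                      photons = numeric()))
  ren <- suppressWarnings(render_smlm_stack(em, acq, fast_system(),
                                            phantom))
  expect_gt(nrow(ren$truth), 3000)
  expect_lt(abs(mean(ren$truth$photons) - 1000) / 1000, 0.02)
})

test_that("injected drift is recoverable from the fiducial trajectories", {
  phantom <- fibril_phantom(label_density = 0, glass_density = 0)
  em <- generate_phantom(phantom, seed = 67)
  acq <- acquisition_model(frames = 300, frame_px = c(48, 48),
                           drift_per_frame = c(0.1, -0.05),
                           drift_rw_sd = 0.1, seed = 68)
  ren <- render_smlm_stack(em, acq, fast_system(), phantom)
  drift <- ren$drift
  # noisy observed fiducial tracks at the rendered positions
  set.seed(69)
  fid <- purrr::map_dfr(1:2, function(b) {
    tibble::tibble(fid_id = b, frame = drift$frame,
                   x_nm = ren$fiducial_truth$x_nm[b] + drift$dx +
                     rnorm(nrow(drift), 0, 2),
                   y_nm = ren$fiducial_truth$y_nm[b] + drift$dy +
                     rnorm(nrow(drift), 0, 2))
  })
  locs <- tibble::tibble(frame = drift$frame, x_nm = 3000 + drift$dx,
                         y_nm = 3000 + drift$dy, z_nm = 0)
  out <- correct_drift(locs, fid)
  resid <- sqrt(mean((out$x_nm - out$x_nm[1])^2 +
                       (out$y_nm - out$y_nm[1])^2))
  drift_rms <- sqrt(mean(drift$dx^2 + drift$dy^2))
  expect_lt(resid, 0.05 * drift_rms + 2)
})

test_that("rendered molecules are recovered by the shared forward model", {
  # render one bright emitter with negligible relative noise and refit it
  sys <- fast_system()
  phantom <- fibril_phantom(length = 2000, radius_wet = 90, radius_dry = 50,
                            label_density = 0, glass_density = 0,
                            field_nm = c(33 * 160, 33 * 160))
  em_tab <- tibble::tibble(id = 1L, x_nm = 16 * 160, y_nm = 16 * 160,
                           z_nm = 90, s_nm = 1000, X_nm = 0,
                           n_true = 1.45, on_glass = FALSE)
  acq <- acquisition_model(frames = 1, frame_px = c(33, 33), p_on = 1,
                           mean_on_frames = 1e6, mean_photons = 2e5,
                           photons_sdlog = 1e-6, background = 50,
                           drift_per_frame = c(0, 0), drift_rw_sd = 0,
                           fiducials = tibble::tibble(x_nm = numeric(),
                                                      y_nm = numeric(),
                                                      photons = numeric()),
                           seed = 70)
  zs <- vapply(1:3, function(k) {
    acq$seed <- 70 + k
    ren <- render_smlm_stack(em_tab, acq, sys, phantom)
    roi <- ren$stack[[1]][16 + (-7:7) + 1, 16 + (-7:7) + 1]
    fit_molecule(roi, sys, layered_sample(1.45, 90))$z_nm
  }, numeric(1))
  expect_lt(abs(mean(zs) - 90), 2)
})

test_that("AFM rendering quantizes the crest within half a pixel", {
  phantom <- fibril_phantom(length = 4000, radius_wet = 85, radius_dry = 50,
                            field_nm = c(5000, 4000))
  m <- render_afm_map(phantom, pixel_size = 39, state = "wet", seed = 71)
  expect_lt(abs(max(m$heights) - 85), sqrt(85^2 - (85 - 39 / 2)^2) + 1)
  expect_true(all(m$heights[m$glass_mask] == 0))
  flat <- render_afm_map(fibril_phantom(radius_wet = 1e-9,
                                        radius_dry = 1e-9),
                         state = "wet", seed = 72)
  expect_lt(max(flat$heights), 1e-6)
})
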