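sys <- fast_system()
samp <- layered_sample(1.43, 100)

test_that("a uniform frame yields no candidates", {
  set.seed(7)
  frame <- matrix(rpois(48 * 48, 10), 48, 48)
  expect_equal(nrow(prelocalize(frame, absolute_threshold = 30)), 0)
})

test_that("well-separated emitters are each found within a pixel", {
  set.seed(8)
  truth_px <- cbind(c(10, 10, 24, 38, 38), c(10, 38, 24, 10, 38))
  frame <- matrix(10, 48, 48)
  for (k in 1:5) {
    img <- compute_molecule_image(
      sys, samp, emitter_state(axial_position = 100, signal_photons = 8000),
      roi_size = 15)
    ri <- truth_px[k, 1] + (-7:7) + 1
    rj <- truth_px[k, 2] + (-7:7) + 1
    frame[ri, rj] <- frame[ri, rj] + unclass(img)
  }
  frame <- matrix(rpois(length(frame), frame), 48, 48)
  cand <- prelocalize(frame, absolute_threshold = 15,
                      relative_threshold = 1.2)
  expect_equal(nrow(cand), 5)
  ord <- order(cand$px_i * 100 + cand$px_j)
  truth_ord <- order(truth_px[, 1] * 100 + truth_px[, 2])
  expect_true(all(abs(cand$px_i[ord] - truth_px[truth_ord, 1]) <= 1))
  expect_true(all(abs(cand$px_j[ord] - truth_px[truth_ord, 2]) <= 1))
})

test_that("overlapping emitters are both rejected", {
  set.seed(9)
  frame <- matrix(10, 48, 48)
  for (c0 in list(c(20, 24), c(28, 24))) {   # 8 px apart, < roi_size
    img <- compute_molecule_image(
      sys, samp, emitter_state(axial_position = 100, signal_photons = 8000),
      roi_size = 15)
    frame[c0[1] + (-7:7) + 1, c0[2] + (-7:7) + 1] <-
      frame[c0[1] + (-7:7) + 1, c0[2] + (-7:7) + 1] + unclass(img)
  }
  frame <- matrix(rpois(length(frame), frame), 48, 48)
  cand <- prelocalize(frame, absolute_threshold = 15,
                      relative_threshold = 1.2)
  expect_equal(nrow(cand), 0)
})

test_that("a noise-free model image is fit to optimizer tolerance", {
  em <- emitter_state(c(25, -35), 110, 6000, 12)
  truth <- unclass(compute_molecule_image(sys, samp, em))
  fit <- fit_molecule(truth, sys, samp,
                      init = emitter_state(c(25, -35), 110, 6000, 12))
  expect_lt(abs(fit$z_nm - 110), 0.5)
  # the fit tabulates shapes on a short radial grid whose normalization
  # differs from the rendering field by the ~0.4% far-tail mass
  expect_lt(abs(fit$photons - 6000) / 6000, 0.02)
  expect_lt(abs(fit$background - 12), 0.2)
  expect_lt(fit$llr, 1e-3)
  expect_true(fit$converged)
})

test_that("negative counts are rejected", {
  bad <- matrix(-1, 15, 15)
  expect_error(fit_molecule(bad, sys, samp), class = "rimap_input_error")
})

test_that("the axial estimator approaches the CRLB and passes the LLR filter", {
  em <- emitter_state(c(0, 0), 100, 5000, 100)   # SBR 50
  expected <- unclass(compute_molecule_image(sys, samp, em))
  set.seed(11)
  fits <- purrr::map_dfr(1:100, function(i) {
    obs <- matrix(rpois(length(expected), expected), nrow(expected))
    fit_molecule(obs, sys, samp)
  })
  fz <- rimap:::.fi_eval(sys, samp, em, step = 2, param = "z")
  z_crlb <- 1 / sqrt(fz)
  expect_lt(sd(fits$z_nm), 1.5 * z_crlb)
  # correctly specified fits overwhelmingly pass the llr < 600 gate
  expect_gte(mean(fits$llr < 600), 0.98)
})

test_that("the axial estimate is unbiased at high photon counts", {
  em <- emitter_state(c(0, 0), 100, 1e5, 1000)
  expected <- unclass(compute_molecule_image(sys, samp, em))
  set.seed(12)
  zs <- vapply(1:60, function(i) {
    obs <- matrix(rpois(length(expected), expected), nrow(expected))
    fit_molecule(obs, sys, samp)$z_nm
  }, numeric(1))
  expect_lt(abs(mean(zs) - 100), 0.5)
})

test_that("assuming a larger refractive index raises the fitted height", {
  em <- emitter_state(c(0, 0), 100, 1e5, 500)
  truth <- unclass(compute_molecule_image(sys, samp, em))
  zs <- vapply(c(1.38, 1.43, 1.48), function(na) {
    fit_molecule(truth, sys, layered_sample(na, 100),
                 init = emitter_state(c(0, 0), 100, 1e5, 500),
                 fix_xy = TRUE)$z_nm
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("blink merging summarizes repeated appearances", {
  # a single localization has an undefined (NA) precision
  one <- tibble::tibble(frame = 1L, x_nm = 0, y_nm = 0, z_nm = 50)
  m1 <- merge_blinks(one)
  expect_equal(nrow(m1), 1)
  expect_true(is.na(m1$sem_z))
  expect_equal(m1$n_observations, 1L)

  # 25 reappearances with isotropic 25 nm noise: sem ~ 25 / sqrt(25) = 5 nm
  set.seed(13)
  reps <- tibble::tibble(frame = 1:25,
                         x_nm = rnorm(25, 1000, 25),
                         y_nm = rnorm(25, 1000, 25),
                         z_nm = rnorm(25, 80, 25))
  m2 <- merge_blinks(reps, linking_radius = 150, max_gap = 3)
  expect_equal(nrow(m2), 1)
  expect_lt(abs(m2$sem_z - 5) / 5, 0.30)

  # two fluorophores 500 nm apart never link at radius 100
  two <- tibble::tibble(frame = rep(1:10, 2),
                        x_nm = rep(c(0, 500), each = 10),
                        y_nm = 0, z_nm = 0)
  expect_equal(nrow(merge_blinks(two, linking_radius = 100)), 2)
})

test_that("localization tables round trip through CSV", {
  locs <- tibble::tibble(frame = 1:3, x_nm = c(1.5, 2, 3), y_nm = 4:6 + 0.25,
                         z_nm = c(10, 20, 30), photons = c(1e3, 2e3, 3e3),
                         background = c(5, 6, 7), llr = c(100, 200, 300),
                         converged = c(TRUE, TRUE, FALSE))
  path <- tempfile(fileext = ".csv")
  write_localizations(locs, path)
  back <- read_localizations(path)
  expect_equal(as.data.frame(back), as.data.frame(locs))
})
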