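sys <- fast_system()
samp <- layered_sample(1.43, 100)
emit <- emitter_state(axial_position = 100, signal_photons = 1e5,
                      background_per_pixel = 1e3)

test_that("no layer means no information about its refractive index", {
  fi <- fisher_information_n(sys, layered_sample(1.4, 0),
                             emitter_state(signal_photons = 1e4,
                                           background_per_pixel = 100))
  expect_equal(as.numeric(fi), 0)
  expect_true(attr(fi, "n_unidentifiable"))
  dn <- delta_n_smlm(sys, layered_sample(1.4, 0),
                     emitter_state(signal_photons = 1e4,
                                   background_per_pixel = 100))
  expect_equal(as.numeric(dn), Inf)
  expect_true(attr(dn, "unbounded"))
})

test_that("the finite-difference Fisher information is step-consistent", {
  fi1 <- fisher_information_n(sys, samp, emit, step = 1e-4)
  fi2 <- fisher_information_n(sys, samp, emit, step = 5e-5)
  expect_lt(abs(fi1 - fi2) / fi2, 0.005)
  expect_no_warning(fisher_information_n(sys, samp, emit, check_step = TRUE))
})

test_that("the CRLB scales as one over root photons at fixed SBR", {
  d1 <- delta_n_smlm(sys, samp, emit)
  emit4 <- emitter_state(axial_position = 100, signal_photons = 4e5,
                         background_per_pixel = 4e3)
  d4 <- delta_n_smlm(sys, samp, emit4)
  expect_lt(abs(d4 - d1 / 2) / (d1 / 2), 0.02)
  # equivariance: delta at N equals delta at 1e5 scaled by sqrt(1e5 / N)
  em25 <- emitter_state(axial_position = 100, signal_photons = 2.5e4,
                        background_per_pixel = 250)
  expect_lt(abs(delta_n_smlm(sys, samp, em25) - d1 * 2) / (d1 * 2), 0.02)
})

test_that("error variances combine in quadrature", {
  b <- total_delta_n(3e-3, 4e-3)
  expect_equal(b$delta_n_total, 5e-3)
  expect_equal(total_delta_n(7e-3, 0)$delta_n_total, 7e-3)
  expect_lt(abs(b$delta_n_total^2 - b$delta_n_smlm^2 - b$delta_n_afm^2),
            1e-12 * b$delta_n_total^2)
  expect_error(total_delta_n(-1e-3, 1e-3), class = "rimap_input_error")
})

test_that("a perfect AFM contributes no refractive-index error", {
  expect_equal(as.numeric(delta_n_afm(sys, samp, emit, afm_uncertainty(0))),
               0)
})

test_that("the two one-sided AFM-induced errors are nearly symmetric", {
  d <- delta_n_afm(sys, samp, emit, afm_uncertainty(1))
  lo <- abs(samp$n_layer - attr(d, "n_hat_minus"))
  hi <- abs(samp$n_layer - attr(d, "n_hat_plus"))
  expect_lt(abs(lo - hi) / max(lo, hi), 0.05)
  expect_gt(as.numeric(d), 0)
})

test_that("the AFM-error optimizer matches a dense grid scan", {
  d <- delta_n_afm(sys, samp, emit, afm_uncertainty(2))
  n_plus <- attr(d, "n_hat_plus")
  # brute-force scan around the optimizer's answer; the surface dye rides
  # the perturbed layer top
  target <- unclass(compute_molecule_image(
    sys, layered_sample(1.43, 102),
    emitter_state(axial_position = 102, signal_photons = 1e5,
                  background_per_pixel = 1e3)))
  grid <- seq(n_plus - 0.005, n_plus + 0.005, by = 1e-4)
  mis <- vapply(grid, function(nf) {
    sum((target - unclass(compute_molecule_image(
      sys, layered_sample(nf, 100),
      emitter_state(axial_position = 100, signal_photons = 1e5,
                    background_per_pixel = 1e3))))^2)
  }, numeric(1))
  expect_lt(abs(grid[which.min(mis)] - n_plus), 2e-4)
})

test_that("the AFM error grows about linearly in the height error", {
  ds <- vapply(c(0.5, 1, 2), function(dz) {
    as.numeric(delta_n_afm(sys, samp, emit, afm_uncertainty(dz)))
  }, numeric(1))
  expect_lt(abs(ds[2] / ds[1] - 2) / 2, 0.15)
  expect_lt(abs(ds[3] / ds[2] - 2) / 2, 0.15)
})

test_that("required photons follow the inverse-square scaling", {
  s50 <- layered_sample(1.43, 100)
  n1 <- required_photons(1e-2, sys, s50, sbr = 100, afm = afm_uncertainty(0))
  n2 <- required_photons(5e-3, sys, s50, sbr = 100, afm = afm_uncertainty(0))
  expect_lt(abs(n2 / n1 - 4) / 4, 0.05)
  # round trip: the budget at the returned N meets the target within 1%
  b <- attr(n1, "budget")
  expect_lt(abs(b$delta_n_total - 1e-2) / 1e-2, 0.01)
})

test_that("targets below the AFM floor are flagged unattainable", {
  res <- required_photons(1e-4, sys, samp, sbr = 100,
                          afm = afm_uncertainty(2))
  expect_true(is.na(res))
  expect_true(attr(res, "unattainable"))
  expect_gt(attr(res, "afm_floor"), 1e-4)
})

test_that("precision tracks the relative height precision across thickness", {
  # delta_n is approximately proportional to delta_H / H: rank correlation
  Hs <- c(50, 100, 150, 200, 300)
  vals <- purrr::map_dfr(Hs, function(H) {
    e <- emitter_state(axial_position = H, signal_photons = 1e5,
                       background_per_pixel = 1e3)
    s <- layered_sample(1.43, H)
    dn <- as.numeric(delta_n_smlm(sys, s, e))
    fz <- rimap:::.fi_eval(sys, s, e, step = 2, param = "z")
    tibble::tibble(dn = dn, rel = (1 / sqrt(fz)) / H)
  })
  expect_gt(cor(vals$dn, vals$rel, method = "spearman"), 0.95)
})

test_that("crlb_sweep returns the full budget on the grid", {
  sw <- crlb_sweep(sys, H_nm = c(50, 100), sbr = c(50, 200), N = 1e5,
                   delta_z_afm = 1)
  expect_s3_class(sw, "crlb_sweep")
  expect_equal(nrow(sw), 4)
  expect_true(all(sw$delta_n_total >= sw$delta_n_smlm))
  expect_true(all(sw$delta_n_total^2 - sw$delta_n_smlm^2 -
                    sw$delta_n_afm^2 < 1e-12))
})
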