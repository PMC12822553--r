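# shared fixtures: a fast optical system (coarser oversampling) and
# generators for synthetic cross-section tables used across test files

fast_system <- function(...) optical_system(oversampling = 2, ...)

# points sampled on the upper surface of a half-cylinder of radius R lying
# along s in [0, L]; theta uniform (uniform per unit surface area)
half_cylinder_cs <- function(n, R = 69, L = 4000, z_noise = 0, seed = 1) {
  set.seed(seed)
  th <- runif(n, 0, pi)
  tibble::tibble(
    s_nm = runif(n, 0, L),
    X_nm = R * cos(th),
    Z_nm = R * sin(th) + rnorm(n, 0, z_noise))
}

# semi-synthetic per-assumed-n cross sections implementing the height
# scaling mechanism: apparent heights stretch linearly with the assumed
# refractive index around the local true one. gamma is the relative height
# sensitivity (per refractive-index unit), in the regime of the psf model.
cs_by_n_mechanism <- function(n_locs = 1200, R = 100, L = 5000,
                              n_true_fun = function(s) rep(1.43, length(s)),
                              ri_grid = c(1.38, 1.43, 1.48),
                              gamma = 2.1, z_noise = 5, seed = 1) {
  set.seed(seed)
  th <- runif(n_locs, 0, pi)
  s <- sort(runif(n_locs, 0, L))
  base <- tibble::tibble(
    loc_id = seq_len(n_locs), s_nm = s,
    x_nm = s, y_nm = 0,
    X_nm = R * cos(th),
    z_true = R * sin(th),
    eps = rnorm(n_locs, 0, z_noise),
    n_true = n_true_fun(s))
  purrr::map_dfr(ri_grid, function(na) {
    out <- base
    out$Z_nm <- (out$z_true + out$eps) * (1 + gamma * (na - out$n_true))
    out$n_assumed <- na
    out[, c("n_assumed", "loc_id", "s_nm", "x_nm", "y_nm", "X_nm", "Z_nm")]
  })
}
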