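# Run configuration (YAML) and subcommand dispatch. Every run validates its
# configuration first and writes the resolved configuration plus a
# machine-readable report next to its outputs, so analyses are auditable.

#' Read a run configuration
#'
#' @param path YAML file with blocks `optics`, `sample`, `precision`,
#'   `localize`, `fibril`, `synth`, `output` plus top-level `seed`.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste("missing input:", path), class = "rimap_input_error")
  }
  validate_run_config(yaml::read_yaml(path))
}

.default_config <- function() {
  list(
    seed = 1,
    optics = list(numerical_aperture = 1.46, emission_wavelength = 670,
                  n_immersion = 1.52, n_ambient = 1.33,
                  pixel_size_sample = 160, defocus = 500,
                  roi_size = 15, oversampling = 6),
    sample = list(n_layer = 1.437, thickness = 100),
    precision = list(H_nm = c(50, 100, 200), sbr = 100, N = 1e5,
                     delta_z_afm = 1, target_delta_n = 0.01,
                     track_focus = TRUE),
    localize = list(absolute_threshold = 50, relative_threshold = 2,
                    llr_max = 600, linking_radius = 100, max_gap = 3),
    fibril = list(ri_grid = seq(1.38, 1.48, by = 0.02), window_nlocs = 40,
                  map_window_nlocs = 100, overlap_fraction = 0.9,
                  dbscan_eps = 30, dbscan_min_samples = 10,
                  debris_offset = 0, n_resamples = 1000, n_draws = 10000),
    synth = list(length = 6000, radius_wet = 100, radius_dry = 60,
                 n_true = 1.43, label_density = 400, glass_density = 1.5,
                 frames = 400, mean_photons = 1000, background = 10),
    output = list(dir = "."))
}

#' Validate a run configuration
#'
#' Fills defaults and checks field values; errors name the failing
#' configuration path (e.g. `optics.n_ambient`).
#'
#' @param config A named list (parsed YAML).
#' @return The completed configuration, classed `run_config`.
#' @export
validate_run_config <- function(config) {
  cfg <- utils::modifyList(.default_config(), config)
  fail <- function(path, why) {
    abort(sprintf("config schema violation at %s: %s", path, why),
          class = "rimap_config_error")
  }
  o <- cfg$optics
  if (!is.numeric(o$n_ambient) || o$n_ambient < 1) {
    fail("optics.n_ambient", "must be a refractive index >= 1")
  }
  if (!is.numeric(o$n_immersion) || o$n_immersion <= o$numerical_aperture) {
    fail("optics.n_immersion", "must exceed the numerical aperture")
  }
  if (o$roi_size %% 2 != 1) fail("optics.roi_size", "must be odd")
  if (o$pixel_size_sample <= 0) fail("optics.pixel_size_sample",
                                     "must be > 0")
  s <- cfg$sample
  if (s$thickness < 0) fail("sample.thickness", "must be >= 0")
  if (s$n_layer < 1 || s$n_layer > 2) fail("sample.n_layer",
                                           "must lie in [1, 2]")
  if (any(cfg$precision$H_nm <= 0)) fail("precision.H_nm", "must be > 0")
  if (any(cfg$precision$sbr <= 0)) fail("precision.sbr", "must be > 0")
  if (cfg$fibril$overlap_fraction < 0 || cfg$fibril$overlap_fraction >= 1) {
    fail("fibril.overlap_fraction", "must lie in [0, 1)")
  }
  if (!is.numeric(cfg$seed)) fail("seed", "must be numeric")
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

.config_system <- function(cfg) {
  o <- cfg$optics
  optical_system(numerical_aperture = o$numerical_aperture,
                 emission_wavelength = o$emission_wavelength,
                 n_immersion = o$n_immersion, n_ambient = o$n_ambient,
                 pixel_size_sample = o$pixel_size_sample,
                 defocus = o$defocus,
                 zernike_terms = if (!is.null(o$zernike_terms))
                   unlist(o$zernike_terms) else NULL,
                 roi_size = o$roi_size, oversampling = o$oversampling)
}

.write_run_report <- function(cfg, name, outdir, inputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  report <- list(subcommand = name,
                 package_version = as.character(utils::packageVersion("rimap")),
                 r_version = R.version.string,
                 seed = cfg$seed,
                 input_digests = digests)
  jsonlite::write_json(report, file.path(outdir, paste0(name, "_report.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg_plain <- unclass(cfg)
  jsonlite::write_json(cfg_plain, file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a named analysis subcommand
#'
#' Dispatches to one of `simulate`, `localize`, `crlb`, `required-photons`,
#' `fibril-ri`, `ri-map`, writes the artifacts into the configured output
#' directory together with the resolved configuration and a machine-readable
#' run report (package version, seed, input digests). Inputs are never
#' modified.
#'
#' @param name Subcommand name.
#' @param config A `run_config` (or path to a YAML file).
#' @param inputs Named character vector of input files (subcommand
#'   dependent: `stack` for `localize`, `locs`/`afm` for the fibril
#'   commands).
#' @return Invisibly, a list of the written artifact paths.
#' @export
run_subcommand <- function(name, config, inputs = character()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  outdir <- config$output$dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (f in inputs) {
    if (!file.exists(f)) abort(paste("missing input file:", f),
                               class = "rimap_input_error")
  }
  system <- .config_system(config)
  artifacts <- switch(
    name,
    "crlb" = {
      p <- config$precision
      sw <- crlb_sweep(system, H_nm = p$H_nm, sbr = p$sbr, N = p$N,
                       n_layer = config$sample$n_layer,
                       delta_z_afm = p$delta_z_afm,
                       track_focus = isTRUE(p$track_focus))
      path <- file.path(outdir, "crlb_sweep.csv")
      write.csv(as.data.frame(sw), path, row.names = FALSE)
      path
    },
    "required-photons" = {
      p <- config$precision
      res <- purrr::map(p$H_nm, function(H) {
        rp <- required_photons(p$target_delta_n, system,
                               layered_sample(config$sample$n_layer, H),
                               sbr = p$sbr[1],
                               afm = afm_uncertainty(p$delta_z_afm))
        list(H_nm = H, target_delta_n = p$target_delta_n,
             required_photons = if (is.na(rp)) NULL else as.numeric(rp),
             unattainable = isTRUE(attr(rp, "unattainable")))
      })
      path <- file.path(outdir, "required_photons.json")
      jsonlite::write_json(res, path, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      path
    },
    "simulate" = {
      sy <- config$synth
      phantom <- fibril_phantom(length = sy$length,
                                radius_wet = sy$radius_wet,
                                radius_dry = sy$radius_dry,
                                n_true = sy$n_true,
                                label_density = sy$label_density,
                                glass_density = sy$glass_density)
      em <- generate_phantom(phantom, seed = config$seed)
      acq <- acquisition_model(frames = sy$frames,
                               mean_photons = sy$mean_photons,
                               background = sy$background,
                               seed = config$seed + 1)
      ren <- render_smlm_stack(em, acq, system, phantom)
      paths <- c(stack = file.path(outdir, "stack.tif"),
                 truth = file.path(outdir, "ground_truth.csv"),
                 fiducials = file.path(outdir, "fiducials.csv"),
                 afm_dry = file.path(outdir, "afm_dry.tif"),
                 afm_wet = file.path(outdir, "afm_wet.tif"))
      write_stack(ren$stack, paths["stack"])
      write.csv(ren$truth, paths["truth"], row.names = FALSE)
      write.csv(ren$fiducial_truth, paths["fiducials"], row.names = FALSE)
      write_afm_map(render_afm_map(phantom, state = "dry",
                                   seed = config$seed + 2), paths["afm_dry"])
      write_afm_map(render_afm_map(phantom, state = "wet",
                                   seed = config$seed + 3), paths["afm_wet"])
      paths
    },
    "localize" = {
      stack <- read_stack(inputs[["stack"]])
      locs <- localize_stack(stack, system,
                             layered_sample(config$sample$n_layer,
                                            config$sample$thickness),
                             absolute_threshold =
                               config$localize$absolute_threshold,
                             relative_threshold =
                               config$localize$relative_threshold)
      locs <- locs[locs$llr < config$localize$llr_max, ]
      path <- file.path(outdir, "locs.csv")
      write_localizations(locs, path)
      path
    },
    "fibril-ri" = ,
    "ri-map" = {
      fb <- config$fibril
      stack <- read_stack(inputs[["stack"]])
      wet <- read_afm_map(inputs[["afm_wet"]])
      # fibril axis from the AFM ridge (pre-registered frames)
      axis_afm <- afm_ridge_axis(wet)
      prof_wet <- afm_fibril_profile(wet, axis_afm, resample = TRUE,
                                     n_resamples = fb$n_resamples,
                                     seed = config$seed)
      res <- analyze_fibril(
        stack, system, prof_wet$height,
        fibril_region = afm_region_predicate(wet),
        ri_grid = fb$ri_grid,
        absolute_threshold = config$localize$absolute_threshold,
        relative_threshold = config$localize$relative_threshold,
        llr_max = config$localize$llr_max,
        window_nlocs = fb$window_nlocs,
        debris_offset = fb$debris_offset,
        dbscan_eps = fb$dbscan_eps,
        dbscan_min_samples = fb$dbscan_min_samples,
        n_resamples = fb$n_resamples, n_draws = fb$n_draws,
        seed = config$seed)
      report <- list(
        n = res$ri$n, sigma_n = res$ri$sigma_n,
        slope_nm_per_ri = res$ri$slope,
        H_smlm_grid = purrr::map(res$heights, function(h)
          list(n_assumed = h$n_assumed, H = h$H, sigma_H = h$sigma_H)),
        H_afm = prof_wet$height$H, sigma_H_afm = prof_wet$height$sigma_H,
        A_wet = prof_wet$area)
      if ("afm_dry" %in% names(inputs)) {
        dry <- read_afm_map(inputs[["afm_dry"]])
        prof_dry <- afm_fibril_profile(dry, axis_afm)
        sw <- swelling_and_dry_index(prof_dry$area, prof_wet$area, res$ri$n)
        report$A_dry <- sw$A_dry
        report$delta_A <- sw$delta_A
        report$n_dry <- sw$n_dry
      }
      paths <- file.path(outdir, "fibril_ri.json")
      jsonlite::write_json(report, paths, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      if (name == "ri-map") {
        long <- purrr::imap_dfr(res$cross_sections_by_n, function(cs, nm) {
          cs$n_assumed <- as.numeric(nm)
          cs
        })
        afm_prof <- afm_height_along(
          wet, res$axis,
          s_centers = seq(250, max(res$axis$dense$s_nm) - 250, by = 250),
          n_resamples = fb$n_resamples %/% 5, seed = config$seed)
        mp <- map_ri_along_fibril(
          long, afm_prof[!is.na(afm_prof$H), ],
          window_nlocs = fb$map_window_nlocs,
          overlap_fraction = fb$overlap_fraction,
          debris_offset = fb$debris_offset, seed = config$seed)
        map_path <- file.path(outdir, "ri_map.csv")
        write.csv(mp[, c("s_nm", "x_nm", "y_nm", "n", "sigma_n_exp",
                         "window_nm")], map_path, row.names = FALSE)
        paths <- c(paths, map_path)
      }
      paths
    },
    abort(paste("unknown subcommand:", name), class = "rimap_config_error"))
  .write_run_report(config, name, outdir, inputs)
  invisible(artifacts)
}
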