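# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' Tidy a refractive-index estimate
#'
#' @param x An `ri_estimate` from [estimate_refractive_index()].
#' @param ... Unused.
#' @return One-row tibble with `n`, `sigma_n`, `slope`, `intercept`.
#' @method tidy ri_estimate
#' @export
tidy.ri_estimate <- function(x, ...) {
  tibble(n = x$n, sigma_n = x$sigma_n, slope = x$slope,
         intercept = x$intercept)
}

#' @rdname tidy.ri_estimate
#' @method glance ri_estimate
#' @export
glance.ri_estimate <- function(x, ...) {
  tibble(n = x$n, sigma_n = x$sigma_n, n_grid_points = nrow(x$heights),
         H_afm = x$h_afm$H, outside_range = x$outside_range)
}

#' @rdname tidy.ri_estimate
#' @method tidy precision_budget
#' @export
tidy.precision_budget <- function(x, ...) {
  tibble(delta_n_smlm = x$delta_n_smlm, delta_n_afm = x$delta_n_afm,
         delta_n_total = x$delta_n_total)
}

#' @rdname tidy.ri_estimate
#' @method tidy height_estimate
#' @export
tidy.height_estimate <- function(x, ...) {
  tibble(H = x$H, sigma_H = x$sigma_H, n_assumed = x$n_assumed,
         window_nlocs = x$window_nlocs)
}

#' @rdname tidy.ri_estimate
#' @method tidy swelling_record
#' @export
tidy.swelling_record <- function(x, ...) {
  tibble(A_dry = x$A_dry, A_wet = x$A_wet, delta_A = x$delta_A,
         n_collagen = x$n_collagen, n_dry = x$n_dry)
}

#' Plot a precision-budget sweep
#'
#' Reproduces the standard presentation of the attainable refractive-index
#' precision: CRLB versus sample thickness, one curve per
#' signal-to-background ratio, solid for the full budget and dashed for an
#' ideal (error-free) AFM.
#'
#' @param object A `crlb_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crlb_sweep
#' @export
autoplot.crlb_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("delta_n_smlm", "delta_n_total"),
                            names_to = "budget", values_to = "delta_n")
  df$budget <- ifelse(df$budget == "delta_n_smlm", "SMLM only (ideal AFM)",
                      "SMLM + AFM")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$H_nm, y = .data$delta_n,
                                   color = factor(.data$sbr),
                                   linetype = .data$budget)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sample thickness H (nm)",
                  y = expression(Delta * n[s]),
                  color = "SBR", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an along-fibril refractive-index map
#'
#' @param object An `ri_map` tibble from [map_ri_along_fibril()].
#' @param ... Unused.
#' @return A ggplot of n (with experimental error bars) versus arclength.
#' @method autoplot ri_map
#' @export
autoplot.ri_map <- function(object, ...) {
  ok <- object[!object$skipped, ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$s_nm / 1000, y = .data$n)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$n - .data$sigma_n_exp,
                                        ymax = .data$n + .data$sigma_n_exp),
                           width = 0, alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(color = .data$n)) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "position along fibril (um)",
                  y = expression(n[collagen]), color = "n") +
    ggplot2::theme_minimal()
}

#' Plot a molecule image
#'
#' @param object A `molecule_image`.
#' @param ... Unused.
#' @return A ggplot raster of expected photons.
#' @method autoplot molecule_image
#' @export
autoplot.molecule_image <- function(object, ...) {
  m <- unclass(object)
  px <- attr(object, "system")$pixel_size_sample
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$photons <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i * px / 1000,
                                   y = .data$j * px / 1000,
                                   fill = .data$photons)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "photons") +
    ggplot2::theme_minimal()
}

#' Plot a cross-section height profile
#'
#' @param object A `height_estimate`.
#' @param ... Unused.
#' @return A ggplot of the sliding-window median profile and its smoothed
#'   version.
#' @method autoplot height_estimate
#' @export
autoplot.height_estimate <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$X_nm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$Z_med), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$Z_smooth), color = "red") +
    ggplot2::geom_hline(yintercept = object$H, linetype = 2) +
    ggplot2::labs(x = "lateral offset X (nm)", y = "height Z (nm)") +
    ggplot2::theme_minimal()
}
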