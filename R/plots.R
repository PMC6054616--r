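#' Plot group-average emission spectra
#'
#' @param spectra Long spectra tibble (normally normalized).
#' @param average Average per group (`TRUE`, default) or draw every spectrum.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, average = TRUE) {
  d <- if (average) average_groups(spectra) else spectra
  aes <- if (average) {
    ggplot2::aes(.data$wavelength_nm, .data$intensity, colour = .data$group)
  } else {
    ggplot2::aes(.data$wavelength_nm, .data$intensity,
                 group = .data$spectrum_id, colour = .data$group)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_line(alpha = if (average) 1 else 0.4) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Normalized intensity (a.u.)",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_spectra
#' @param object,x Objects dispatched to the autoplot methods below.
#' @param ... Unused.
autoplot.peak_fit <- function(object, ...) {
  obs <- tibble::tibble(wavelength_nm = object$wavelength_nm,
                        intensity = object$observed, what = "observed")
  fit <- tibble::tibble(wavelength_nm = object$wavelength_nm,
                        intensity = object$fitted, what = "fitted sum")
  comps <- purrr::pmap(object$bands, function(band, center_nm, amplitude,
                                              sigma_nm, ...) {
    tibble::tibble(
      wavelength_nm = object$wavelength_nm,
      intensity = amplitude * gauss(object$wavelength_nm, center_nm, sigma_nm),
      band = band
    )
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(obs, ggplot2::aes(.data$wavelength_nm, .data$intensity)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_line(data = fit, colour = "black", linetype = 2) +
    ggplot2::geom_line(data = comps, ggplot2::aes(colour = .data$band)) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Normalized intensity (a.u.)",
                  colour = "Band",
                  title = sprintf("%s: chi-square %.3g", object$spectrum_id,
                                  object$chi_square)) +
    ggplot2::theme_minimal()
}

#' Box plot of the hemoglobin index per group
#'
#' @param thc Index table from [thc_index()].
#' @return A ggplot object.
#' @export
plot_thc <- function(thc) {
  ggplot2::ggplot(thc[!is.na(thc$group), ],
                  ggplot2::aes(.data$group, .data$log_ratio, fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "ln(I500 / I570)  (relative total hemoglobin)") +
    ggplot2::theme_minimal()
}

#' ROC curves of a staging classification
#'
#' @param classification A `staging_classification` object.
#' @param role Which report role's ROC to draw.
#' @return A ggplot object.
#' @export
plot_roc <- function(classification, role = "overall") {
  d <- classification$reports |>
    dplyr::filter(.data$role == !!role) |>
    dplyr::mutate(label = sprintf("%s (AUC %.3f)", .data$pair, .data$auc)) |>
    dplyr::select("label", "roc") |>
    tidyr::unnest("roc")
  ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_roc
autoplot.staging_classification <- function(object, ...) plot_roc(object)

# points of a 2-SD ellipse from its summary row
ellipse_path <- function(row, n = 120) {
  t <- seq(0, 2 * pi, length.out = n)
  ca <- cos(row$angle_rad)
  sa <- sin(row$angle_rad)
  x <- row$semi_axis_1 * cos(t)
  y <- row$semi_axis_2 * sin(t)
  tibble::tibble(
    group = row$group,
    ld1 = row$cx + ca * x - sa * y,
    ld2 = row$cy + sa * x + ca * y
  )
}

#' Discriminant score plot with 2-SD ellipses
#'
#' Scatter of the full dataset in the two multiclass discriminant
#' dimensions, class centroids (stars) and two-standard-deviation
#' confidence ellipses.
#'
#' @param ellipse An `ellipse_summary` (or `staging_classification`) object.
#' @return A ggplot object.
#' @export
plot_discriminant <- function(ellipse) {
  if (inherits(ellipse, "staging_classification")) ellipse <- ellipse$ellipse
  paths <- purrr::map(seq_len(nrow(ellipse$ellipses)),
                      function(i) ellipse_path(ellipse$ellipses[i, ])) |>
    dplyr::bind_rows()
  ggplot2::ggplot(ellipse$coords,
                  ggplot2::aes(.data$ld1, .data$ld2, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_path(data = paths) +
    ggplot2::geom_point(data = ellipse$ellipses,
                        ggplot2::aes(.data$cx, .data$cy, colour = .data$group),
                        shape = 8, size = 3, stroke = 1.2) +
    ggplot2::labs(x = "Discriminant function 1", y = "Discriminant function 2",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_discriminant
autoplot.ellipse_summary <- function(object, ...) plot_discriminant(object)
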