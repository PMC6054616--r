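#' Resample spectra onto a common wavelength grid
#'
#' Linear interpolation of each spectrum onto `grid`. Input spectra must
#' cover the grid's span; no extrapolation is performed. Spectra already on
#' the grid pass through unchanged.
#'
#' @param spectra Long spectra tibble.
#' @param grid Target wavelength vector (default [standard_grid()]).
#' @return Spectra tibble on `grid`.
#' @export
resample_to_grid <- function(spectra, grid = standard_grid()) {
  validate_spectra(spectra)
  spectra |>
    dplyr::group_by(.data$spectrum_id, .data$group, .data$animal_id) |>
    dplyr::group_modify(function(d, key) {
      if (min(d$wavelength_nm) > min(grid) || max(d$wavelength_nm) < max(grid)) {
        stop(sprintf("spectrum %s spans [%g, %g] nm; cannot resample to [%g, %g] without extrapolation",
                     key$spectrum_id, min(d$wavelength_nm), max(d$wavelength_nm),
                     min(grid), max(grid)), call. = FALSE)
      }
      if (length(d$wavelength_nm) == length(grid) &&
          all(d$wavelength_nm == grid)) {
        return(tibble::tibble(wavelength_nm = grid, intensity = d$intensity))
      }
      tibble::tibble(
        wavelength_nm = grid,
        intensity = stats::approx(d$wavelength_nm, d$intensity, xout = grid)$y
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("spectrum_id", "group", "animal_id", "wavelength_nm", "intensity")
}

#' Normalize spectra to the 500 +/- 10 nm window maximum
#'
#' Divides every spectrum by its maximum intensity on grid points within the
#' closed window `[center - halfwidth, center + halfwidth]` nm (default
#' 490-510 nm), recording the divisor in a `normalization_factor` column.
#' After normalization the window maximum is exactly 1; intensities outside
#' the window may exceed 1. Idempotent and invariant to positive rescaling
#' of the input.
#'
#' @param spectra Long spectra tibble covering the window.
#' @param center,halfwidth Window centre and half-width in nm.
#' @return Spectra tibble with rescaled `intensity` plus
#'   `normalization_factor` (the original window maximum).
#' @export
normalize_spectra <- function(spectra, center = 500, halfwidth = 10) {
  validate_spectra(spectra)
  lo <- center - halfwidth
  hi <- center + halfwidth
  out <- spectra |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::mutate(.window_max = {
      w <- .data$wavelength_nm >= lo & .data$wavelength_nm <= hi
      if (!any(w)) {
        stop(sprintf("spectrum %s does not cover the [%g, %g] nm window",
                     .data$spectrum_id[[1]], lo, hi), call. = FALSE)
      }
      max(.data$intensity[w])
    }) |>
    dplyr::ungroup()
  if (any(out$.window_max <= 0)) {
    bad <- out$spectrum_id[out$.window_max <= 0][[1]]
    stop(sprintf("spectrum %s: nonpositive maximum in the normalization window", bad),
         call. = FALSE)
  }
  out |>
    dplyr::mutate(
      intensity = .data$intensity / .data$.window_max,
      normalization_factor = if ("normalization_factor" %in% names(spectra)) {
        spectra$normalization_factor * .data$.window_max
      } else {
        .data$.window_max
      }
    ) |>
    dplyr::select(-".window_max")
}

#' Pointwise group-average spectrum
#'
#' Arithmetic mean intensity at each wavelength over all member spectra of
#' one group. All members must share a common grid.
#'
#' @param spectra Long spectra tibble (normally normalized).
#' @param group Group label to average.
#' @return Tibble with columns `group`, `wavelength_nm`, `intensity`.
#' @export
average_group <- function(spectra, group) {
  sel <- spectra[!is.na(spectra$group) & spectra$group == group, ]
  if (nrow(sel) == 0) {
    stop(sprintf("no spectra in group '%s'", group), call. = FALSE)
  }
  common_grid(sel)
  sel |>
    dplyr::group_by(.data$group, .data$wavelength_nm) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
}

#' Group-average spectra for every group present
#'
#' @param spectra Long spectra tibble.
#' @return Tibble of per-group mean spectra, stacked.
#' @export
average_groups <- function(spectra) {
  groups <- unique(spectra$group[!is.na(spectra$group)])
  purrr::map(groups, function(g) average_group(spectra, g)) |>
    dplyr::bind_rows()
}
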