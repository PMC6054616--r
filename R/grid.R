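#' Standard emission wavelength grid
#'
#' The common grid all spectra are resampled to before analysis: 441 to
#' 750 nm inclusive at 1 nm spacing, i.e. exactly 310 samples spanning the
#' 440-750 nm emission window recorded under 410 nm excitation. The grid
#' contains 500 and 570 nm as exact points, which the hemoglobin index and
#' the normalization window rely on.
#'
#' @return Numeric vector of wavelengths in nm, length 310.
#' @export
#' @examples
#' length(standard_grid())
standard_grid <- function() {
  as.numeric(441:750)
}

#' Fibrosis stage labels
#'
#' The four study groups, in fixed order: healthy controls, mild fibrosis,
#' moderate fibrosis, and reversal (regression after withdrawal of the
#' intoxicant).
#'
#' @return Character vector of the four group labels.
#' @export
fibrosis_groups <- function() {
  c("control", "mild", "moderate", "reversal")
}

# Severity ranking used to pick the positive (more advanced) class of a pair.
# Reversal sits between control and mild: it is a regressed lesion.
stage_severity <- function() {
  c(control = 0, reversal = 1, mild = 2, moderate = 3)
}

#' Count spectra per group
#'
#' @param spectra A spectra tibble (see [read_dataset()]).
#' @return A tibble with columns `group` and `n` (number of distinct spectra).
#' @export
group_counts <- function(spectra) {
  spectra |>
    dplyr::distinct(.data$spectrum_id, .data$group) |>
    dplyr::count(.data$group, name = "n")
}

# Internal: validate a long spectra tibble. Checks the per-spectrum
# invariants (strictly increasing wavelengths, finite nonnegative
# intensities, matching lengths are implied by the long layout).
validate_spectra <- function(spectra, arg = "spectra") {
  required <- c("spectrum_id", "wavelength_nm", "intensity")
  missing <- setdiff(required, names(spectra))
  if (length(missing) > 0) {
    stop(sprintf("`%s` lacks column(s): %s", arg, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(is.finite(spectra$intensity))) {
    stop(sprintf("`%s` contains non-finite intensities", arg), call. = FALSE)
  }
  if (any(spectra$intensity < 0)) {
    stop(sprintf("`%s` contains negative intensities", arg), call. = FALSE)
  }
  bad <- spectra |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$wavelength_nm, strictly = TRUE),
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop(sprintf("`%s`: wavelengths not strictly increasing for spectrum %s",
                 arg, bad$spectrum_id[[1]]), call. = FALSE)
  }
  invisible(spectra)
}

# Internal: check all spectra share an identical grid; return that grid.
common_grid <- function(spectra) {
  grids <- spectra |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::summarise(key = paste(.data$wavelength_nm, collapse = ","), .groups = "drop")
  if (dplyr::n_distinct(grids$key) != 1) {
    stop("spectra are not on a common wavelength grid; resample first", call. = FALSE)
  }
  spectra$wavelength_nm[spectra$spectrum_id == spectra$spectrum_id[[1]]]
}

# Internal: validated group labels (NA allowed for prediction-only sets).
check_group_labels <- function(group) {
  known <- is.na(group) | group %in% fibrosis_groups()
  if (!all(known)) {
    stop(sprintf("unknown group label(s): %s",
                 paste(unique(group[!known]), collapse = ", ")), call. = FALSE)
  }
  invisible(group)
}
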