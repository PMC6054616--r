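# Shared fixtures, built in code.

# single Gaussian band evaluated on a grid
gauss_curve <- function(lambda, mu, sigma, a = 1) {
  a * exp(-(lambda - mu)^2 / (2 * sigma^2))
}

# long spectra tibble from a named list of intensity vectors on a grid
spectra_tbl <- function(intensities, grid = standard_grid(), group = NA_character_) {
  groups <- rep_len(group, length(intensities))
  purrr::imap(intensities, function(y, id) {
    tibble::tibble(
      spectrum_id = id,
      group = groups[[match(id, names(intensities))]],
      animal_id = NA_character_,
      wavelength_nm = grid,
      intensity = y
    )
  }) |> dplyr::bind_rows()
}

# one-band preset with configurable hemoglobin, for forward-model oracles
one_band_preset <- function(c = 0, s = 0.7, noise_sd = 0, mu = 500, sigma = 20,
                            a = 1, group = "control") {
  group_preset(
    group,
    tibble::tibble(band = "FAD", center = mu, sigma = sigma, amplitude = a),
    hb_concentration = c, saturation = s, noise_sd = noise_sd
  )
}

# cached default-scale dataset (60/group, seed 17), shared across test files
default_dataset_cache <- new.env(parent = emptyenv())
default_dataset <- function() {
  if (is.null(default_dataset_cache$d)) {
    default_dataset_cache$d <- normalize_spectra(generate_dataset(60, seed = 17))
  }
  default_dataset_cache$d
}
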