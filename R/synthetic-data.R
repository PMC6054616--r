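gauss <- function(lambda, mu, sigma) exp(-(lambda - mu)^2 / (2 * sigma^2))

#' Parametric hemoglobin extinction model with exact isosbestic points
#'
#' Builds smooth relative extinction curves for oxygenated hemoglobin (Q
#' bands at 542 and 577 nm) and deoxygenated hemoglobin (single band near
#' 555 nm) on a wavelength grid. The deoxy curve is multiplied by a smooth
#' log-linear factor chosen so that the two curves agree *exactly* at 500 and
#' 570 nm — the two wavelengths the ratiometric hemoglobin index reads — and
#' the extinction at 570 nm exceeds that at 500 nm. Units are relative: only
#' the product concentration x path length x extinction matters downstream.
#'
#' @param grid Wavelength grid in nm; must contain 500 and 570 nm as exact
#'   points and cover the 440-750 nm span.
#' @return A tibble with columns `wavelength_nm`, `eps_oxy`, `eps_deoxy`.
#' @export
#' @examples
#' ext <- default_extinction_model()
#' subset(ext, wavelength_nm %in% c(500, 570))
default_extinction_model <- function(grid = standard_grid()) {
  if (!all(c(500, 570) %in% grid)) {
    stop("extinction grid must contain 500 and 570 nm as exact points", call. = FALSE)
  }
  oxy <- gauss(grid, 542, 11) + 1.10 * gauss(grid, 577, 11)
  deoxy_raw <- 1.25 * gauss(grid, 555, 20)
  at <- function(v, w) v[match(w, grid)]
  u <- log(at(oxy, 500) / at(deoxy_raw, 500))
  v <- (log(at(oxy, 570) / at(deoxy_raw, 570)) - u) / 70
  deoxy <- deoxy_raw * exp(u + v * (grid - 500))
  tibble::tibble(wavelength_nm = grid, eps_oxy = oxy, eps_deoxy = deoxy)
}

#' Construct a group preset for the forward simulator
#'
#' A preset bundles the Gaussian emission bands of the five endogenous
#' fluorophores with the Beer-Lambert hemoglobin attenuation parameters and
#' the noise level for one fibrosis stage.
#'
#' @param group Group label (one of [fibrosis_groups()]).
#' @param bands Tibble with columns `band`, `center`, `sigma`, `amplitude`
#'   (nm, nm, arbitrary units).
#' @param hb_concentration Dimensionless relative total hemoglobin
#'   concentration, >= 0.
#' @param saturation Oxygen saturation fraction in `[0, 1]`.
#' @param path_length Dimensionless effective optical path length, > 0.
#' @param noise_sd Additive Gaussian noise standard deviation as a fraction
#'   of the noiseless peak intensity, >= 0.
#' @return An object of class `group_preset`.
#' @export
group_preset <- function(group, bands, hb_concentration, saturation = 0.7,
                         path_length = 1, noise_sd = 0.005) {
  check_group_labels(group)
  stopifnot(
    is.data.frame(bands),
    all(c("band", "center", "sigma", "amplitude") %in% names(bands))
  )
  if (any(bands$sigma <= 0)) stop("band sigma must be > 0", call. = FALSE)
  if (any(bands$amplitude < 0)) stop("band amplitude must be >= 0", call. = FALSE)
  if (hb_concentration < 0) stop("hb_concentration must be >= 0", call. = FALSE)
  if (saturation < 0 || saturation > 1) stop("saturation must be in [0, 1]", call. = FALSE)
  if (path_length <= 0) stop("path_length must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(group = group, bands = tibble::as_tibble(bands),
         hb_concentration = hb_concentration, saturation = saturation,
         path_length = path_length, noise_sd = noise_sd),
    class = "group_preset"
  )
}

#' Default forward-model presets for the four fibrosis stages
#'
#' Emission band positions follow the fitted peak positions the study design
#' rests on: FAD centred at 501 (control), 505 (mild), 512 (moderate) and
#' 502 nm (reversal); lipopigments at 590 nm with amplitude ordering
#' control ~ reversal < mild < moderate; protoporphyrin at 630 nm; and the
#' red porphyrin companion at 690 nm for control/reversal that blue-shifts
#' to 670 nm (coproporphyrin accumulation) in mild/moderate fibrosis.
#' Relative hemoglobin concentrations are ordered
#' moderate < mild < reversal < control.
#'
#' @param noise_sd Noise level passed to every preset (fraction of peak).
#' @return Named list of four [group_preset()] objects.
#' @export
default_presets <- function(noise_sd = 0.005) {
  band_tbl <- function(fad_center, a_lip, a_por, cop_center, a_cop) {
    tibble::tibble(
      band = c("NADH", "FAD", "lipopigments", "porphyrin", "coproporphyrin"),
      center = c(470, fad_center, 590, 630, cop_center),
      sigma = c(15, 18, 12, 8, 8),
      amplitude = c(0.5, 1.0, a_lip, a_por, a_cop)
    )
  }
  list(
    control = group_preset("control", band_tbl(501, 0.10, 0.08, 690, 0.06),
                           hb_concentration = 0.15, noise_sd = noise_sd),
    mild = group_preset("mild", band_tbl(505, 0.22, 0.18, 670, 0.15),
                        hb_concentration = 0.07, noise_sd = noise_sd),
    moderate = group_preset("moderate", band_tbl(512, 0.35, 0.30, 670, 0.25),
                            hb_concentration = 0.04, noise_sd = noise_sd),
    reversal = group_preset("reversal", band_tbl(502, 0.11, 0.09, 690, 0.07),
                            hb_concentration = 0.12, noise_sd = noise_sd)
  )
}

# Internal: noiseless forward model on the extinction model's grid.
# S(lambda) = sum_k A_k G(lambda; mu_k, sigma_k) *
#             exp(-c L (s eps_oxy + (1-s) eps_deoxy))
forward_model <- function(preset, extinction, band_factors = NULL) {
  grid <- extinction$wavelength_nm
  amps <- preset$bands$amplitude
  if (!is.null(band_factors)) {
    stopifnot(length(band_factors) == length(amps))
    amps <- amps * band_factors
  }
  signal <- rep(0, length(grid))
  for (k in seq_len(nrow(preset$bands))) {
    signal <- signal + amps[[k]] *
      gauss(grid, preset$bands$center[[k]], preset$bands$sigma[[k]])
  }
  eps <- preset$saturation * extinction$eps_oxy +
    (1 - preset$saturation) * extinction$eps_deoxy
  signal * exp(-preset$hb_concentration * preset$path_length * eps)
}

#' Simulate one emission spectrum
#'
#' Evaluates the noiseless forward model (Gaussian fluorophore bands times
#' Beer-Lambert hemoglobin attenuation) on the extinction model's grid and
#' adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `noise_sd x max(noiseless signal)`, clipped at zero. With `noise_sd = 0`
#' no random numbers are drawn, so the output is seed-independent.
#'
#' @param preset A [group_preset()].
#' @param extinction Extinction tibble from [default_extinction_model()].
#' @param seed Integer seed for the noise draw; identical seed, identical
#'   spectrum. `NULL` uses the current RNG state.
#' @param spectrum_id,animal_id Metadata attached to the output.
#' @param band_factors Optional multiplicative per-band amplitude factors
#'   (used by [generate_dataset()] for animal-level random effects).
#' @return A long spectra tibble, one row per grid wavelength.
#' @export
generate_spectrum <- function(preset, extinction = default_extinction_model(),
                              seed = NULL, spectrum_id = preset$group,
                              animal_id = NA_character_, band_factors = NULL) {
  stopifnot(inherits(preset, "group_preset"))
  clean <- forward_model(preset, extinction, band_factors)
  intensity <- clean
  if (preset$noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    noise <- stats::rnorm(length(clean), 0, preset$noise_sd * max(clean))
    intensity <- pmax(clean + noise, 0)
  }
  tibble::tibble(
    spectrum_id = spectrum_id,
    group = preset$group,
    animal_id = animal_id,
    wavelength_nm = extinction$wavelength_nm,
    intensity = intensity
  )
}

#' Simulate a labelled multi-group dataset
#'
#' Generates `n_per_group` spectra per preset (default 60, emulating 5
#' animals x 12 liver sites per group). Spectra within a group are split
#' over `n_animals` animals; each animal carries a multiplicative log-normal
#' random effect (sd `animal_sd` on the log scale) on every band amplitude,
#' emulating animal-level clustering. The whole dataset is a deterministic
#' function of `seed`: animal effects are drawn from `seed` and each
#' spectrum's noise stream is seeded by a per-spectrum counter, so the same
#' call is bit-reproducible.
#'
#' @param n_per_group Spectra per group, >= 1.
#' @param seed Integer master seed.
#' @param presets Named list of [group_preset()] objects.
#' @param n_animals Animals per group.
#' @param animal_sd Log-scale standard deviation of the per-animal amplitude
#'   effect.
#' @param extinction Extinction model tibble.
#' @return A long spectra tibble with `n_per_group x length(presets)`
#'   spectra on the common grid.
#' @export
#' @examples
#' d <- generate_dataset(n_per_group = 2, seed = 1)
#' group_counts(d)
generate_dataset <- function(n_per_group = 60, seed = 1,
                             presets = default_presets(), n_animals = 5,
                             animal_sd = 0.05,
                             extinction = default_extinction_model()) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  stopifnot(length(presets) >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n_bands <- nrow(presets[[1]]$bands)
  # Animal random effects drawn once, independent of n_per_group.
  effects <- array(
    exp(stats::rnorm(length(presets) * n_animals * n_bands, 0, animal_sd)),
    dim = c(length(presets), n_animals, n_bands)
  )
  counter <- 0L
  out <- purrr::imap(presets, function(preset, gname) {
    gi <- match(gname, names(presets))
    animal_of <- rep(seq_len(n_animals), each = ceiling(n_per_group / n_animals))
    purrr::map(seq_len(n_per_group), function(i) {
      counter <<- counter + 1L
      # Deterministic per-spectrum sub-seed: global stream split by counter.
      sub_seed <- as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
      a <- animal_of[[i]]
      generate_spectrum(
        preset, extinction,
        seed = sub_seed,
        spectrum_id = sprintf("%s_%03d", gname, i),
        animal_id = sprintf("%s_a%d", gname, a),
        band_factors = effects[gi, a, ]
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  validate_spectra(out)
  out
}
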