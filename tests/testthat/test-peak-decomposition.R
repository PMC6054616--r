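test_that("band_metrics matches the Gaussian closed forms", {
  m <- band_metrics(1, 1)
  expect_equal(m$fwhm_nm, 2 * sqrt(2 * log(2)), tolerance = 1e-10)
  expect_equal(m$area, sqrt(2 * pi), tolerance = 1e-10)

  # area is linear in amplitude, FWHM independent of it
  m2 <- band_metrics(2, 1)
  expect_equal(m2$area, 2 * m$area)
  expect_equal(m2$fwhm_nm, m$fwhm_nm)

  # quadrature oracle: trapezoid integral of the band over a wide span
  x <- seq(300, 700, by = 0.01)
  y <- gauss_curve(x, 500, 10)
  quad <- sum((utils::head(y, -1) + utils::tail(y, -1)) / 2 * diff(x))
  expect_equal(band_metrics(1, 10)$area, quad, tolerance = 1e-6)

  expect_error(band_metrics(1, 0), "sigma")
})

test_that("default band library covers the study's band positions", {
  lib <- default_band_library()
  expect_equal(nrow(lib), 5)
  expect_setequal(lib$band, c("NADH", "FAD", "lipopigments", "porphyrin",
                              "coproporphyrin"))
  fad <- lib[lib$band == "FAD", ]
  expect_true(all(c(501, 505, 512, 502) >= fad$center_min &
                    c(501, 505, 512, 502) <= fad$center_max))
  cop <- lib[lib$band == "coproporphyrin", ]
  expect_true(cop$center_min <= 670 && cop$center_max >= 690)
  expect_true(all(lib$center >= lib$center_min & lib$center <= lib$center_max))
  expect_true(all(lib$sigma >= lib$sigma_min & lib$sigma <= lib$sigma_max))
})

test_that("fit recovers a noiseless two-band spectrum to 1e-6", {
  grid <- standard_grid()
  truth <- tibble::tibble(
    band = c("NADH", "FAD"),
    center = c(470, 500), sigma = c(20, 25), amplitude = c(0.6, 1.0)
  )
  y <- gauss_curve(grid, 470, 20, 0.6) + gauss_curve(grid, 500, 25, 1.0)
  s <- spectra_tbl(list(two = y))
  inits <- dplyr::mutate(truth,
                         center_min = center - 15, center_max = center + 15,
                         sigma_min = 5, sigma_max = 40,
                         amplitude_min = 0, amplitude_max = 5)
  fit <- fit_peaks(s, bands = inits, init = "library")
  expect_true(fit$converged)
  expect_lt(fit$chi_square, 1e-12)
  expect_equal(fit$bands$center_nm, truth$center, tolerance = 1e-6)
  expect_equal(fit$bands$sigma_nm, truth$sigma, tolerance = 1e-6)
  expect_equal(fit$bands$amplitude, truth$amplitude, tolerance = 1e-6)

  # and from guesses perturbed by +/- 5 nm and +/- 20% amplitude
  perturbed <- dplyr::mutate(inits,
                             center = center + c(5, -5),
                             amplitude = amplitude * c(1.2, 0.8))
  fit2 <- fit_peaks(s, bands = perturbed, init = "library")
  expect_equal(fit2$bands$center_nm, truth$center, tolerance = 1e-6)
  expect_equal(fit2$bands$amplitude, truth$amplitude, tolerance = 1e-6)
})

test_that("a fit initialised at the optimum stays there", {
  grid <- standard_grid()
  s <- spectra_tbl(list(one = gauss_curve(grid, 500, 20)))
  inits <- tibble::tibble(
    band = "FAD", center = 500, center_min = 485, center_max = 515,
    sigma = 20, sigma_min = 5, sigma_max = 40,
    amplitude = 1, amplitude_min = 0, amplitude_max = 5
  )
  fit <- fit_peaks(s, bands = inits, init = "library")
  expect_true(fit$converged)
  expect_lt(fit$chi_square, 1e-20)
  expect_lte(fit$n_iterations, 2)
})

test_that("the LM fit never worsens the chi-square of the initial guess", {
  s <- normalize_spectra(generate_spectrum(default_presets()$mild, seed = 31))
  lib <- default_band_library()
  model0 <- rowSums(purrr::pmap_dfc(
    list(lib$center, lib$sigma, lib$amplitude),
    function(mu, sg, a) tibble::tibble(v = gauss_curve(s$wavelength_nm, mu, sg, a))
  ))
  chi0 <- sum((s$intensity - model0)^2)
  fit <- fit_peaks(s, init = "library")
  expect_lte(fit$chi_square, chi0)
})

test_that("fitted bands are sorted by center and keep fluorophore names", {
  s <- normalize_spectra(generate_spectrum(default_presets()$control, seed = 13))
  fit <- fit_peaks(s)
  expect_false(is.unsorted(fit$bands$center_nm))
  expect_equal(fit$bands$band,
               c("NADH", "FAD", "lipopigments", "porphyrin", "coproporphyrin"))
  expect_equal(fit$bands$fwhm_nm, 2 * sqrt(2 * log(2)) * fit$bands$sigma_nm)
  expect_equal(fit$bands$area, fit$bands$amplitude * fit$bands$sigma_nm * sqrt(2 * pi))
  # tidiers expose the same table
  expect_equal(tidy(fit)$center_nm, fit$bands$center_nm)
  expect_equal(glance(fit)$chi_square, fit$chi_square)
})

test_that("non-convergence is reported via the flag, not an error", {
  s <- normalize_spectra(generate_spectrum(default_presets()$moderate, seed = 7))
  fit <- fit_peaks(s, max_iter = 1)
  expect_false(fit$converged)
  expect_s3_class(fit$bands, "tbl_df")
})

test_that("blue-band area is conserved and lipopigment areas rank by stage", {
  presets <- default_presets(noise_sd = 0)
  fits <- purrr::imap(presets, function(p, g) {
    f <- fit_peaks(normalize_spectra(generate_spectrum(p)))
    dplyr::mutate(f$bands, group = g)
  }) |> dplyr::bind_rows()

  blue <- fits |>
    dplyr::filter(band %in% c("NADH", "FAD")) |>
    dplyr::group_by(group) |>
    dplyr::summarise(total = sum(area), .groups = "drop")
  expect_lt((max(blue$total) - min(blue$total)) / max(blue$total), 0.15)

  lip <- fits |>
    dplyr::filter(band == "lipopigments") |>
    dplyr::select(group, area) |>
    tibble::deframe()
  expect_lt(abs(lip[["control"]] - lip[["reversal"]]) / lip[["control"]], 0.2)
  expect_lt(lip[["control"]], lip[["mild"]])
  expect_lt(lip[["reversal"]], lip[["mild"]])
  expect_lt(lip[["mild"]], lip[["moderate"]])
})
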