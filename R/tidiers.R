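#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname peak_fit_tidiers
#' @param x A `peak_fit` object.
#' @param ... Unused.
tidy.peak_fit <- function(x, ...) {
  dplyr::mutate(x$bands, spectrum_id = x$spectrum_id, .before = 1)
}

#' Tidiers for peak fits
#'
#' `tidy()` returns the fitted band table; `glance()` a one-row fit summary.
#'
#' @name peak_fit_tidiers
#' @export
glance.peak_fit <- function(x, ...) {
  tibble::tibble(
    spectrum_id = x$spectrum_id,
    chi_square = x$chi_square,
    converged = x$converged,
    n_iterations = x$n_iterations,
    n_bands = nrow(x$bands)
  )
}

#' @export
#' @rdname spectral_pca_tidiers
tidy.spectral_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_variance_fractions),
    explained_variance_fraction = x$explained_variance_fractions,
    cumulative = cumsum(x$explained_variance_fractions),
    retained = seq_along(x$explained_variance_fractions) <= x$n_retained
  )
}

#' Tidiers for spectral PCA
#'
#' `tidy()` lists per-component explained variance; `glance()` summarises the
#' retention.
#'
#' @name spectral_pca_tidiers
#' @param x A `spectral_pca` object.
#' @param ... Unused.
#' @export
glance.spectral_pca <- function(x, ...) {
  tibble::tibble(
    n_spectra = nrow(x$scores),
    n_retained = x$n_retained,
    variance_retained = sum(x$explained_variance_fractions[seq_len(x$n_retained)])
  )
}

#' @export
#' @rdname pairwise_lda_tidiers
tidy.pairwise_lda <- function(x, ...) {
  tibble::tibble(
    term = names(x$weights),
    weight = as.numeric(x$weights)
  )
}

#' Tidiers for pairwise discriminants
#'
#' `tidy()` returns the weight vector on PC scores; `glance()` the pair,
#' positive class and offset.
#'
#' @name pairwise_lda_tidiers
#' @param x A `pairwise_lda` object.
#' @param ... Unused.
#' @export
glance.pairwise_lda <- function(x, ...) {
  tibble::tibble(
    pair = paste(x$pair, collapse = "-"),
    positive = x$positive,
    offset = x$offset,
    cutoff = x$cutoff,
    n_components = length(x$weights)
  )
}
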