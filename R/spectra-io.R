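#' Read a single emission spectrum from CSV
#'
#' Reads a two-column CSV (`wavelength_nm,intensity`; header optional) into a
#' spectra tibble. Rows are sorted by wavelength on load; duplicate
#' wavelengths, non-numeric rows, non-finite or negative intensities are
#' rejected.
#'
#' @param path Path to the CSV file.
#' @param spectrum_id Identifier to attach; defaults to the file name without
#'   extension.
#' @param group Optional group label (one of [fibrosis_groups()], or `NA`).
#' @param animal_id Optional animal identifier.
#' @return A tibble with columns `spectrum_id`, `group`, `animal_id`,
#'   `wavelength_nm`, `intensity`, one row per wavelength.
#' @export
read_spectrum <- function(path, spectrum_id = NULL, group = NA_character_,
                          animal_id = NA_character_) {
  if (!file.exists(path)) {
    stop(sprintf("spectrum file not found: %s", path), call. = FALSE)
  }
  if (is.null(spectrum_id)) {
    spectrum_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("[A-Za-z]", first)
  raw <- readr::read_csv(
    path,
    col_names = if (has_header) TRUE else c("wavelength_nm", "intensity"),
    col_types = readr::cols(.default = readr::col_character()),
    skip = 0, progress = FALSE, show_col_types = FALSE
  )
  if (ncol(raw) < 2) {
    stop(sprintf("%s: expected two columns (wavelength_nm, intensity)", path),
         call. = FALSE)
  }
  names(raw)[1:2] <- c("wavelength_nm", "intensity")
  wl <- suppressWarnings(as.numeric(raw$wavelength_nm))
  it <- suppressWarnings(as.numeric(raw$intensity))
  bad <- which(is.na(wl) | is.na(it))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-numeric value on data line %d", path, bad[[1]]),
         call. = FALSE)
  }
  if (anyDuplicated(wl)) {
    stop(sprintf("%s: duplicate wavelengths", path), call. = FALSE)
  }
  ord <- order(wl)
  out <- tibble::tibble(
    spectrum_id = spectrum_id,
    group = group,
    animal_id = animal_id,
    wavelength_nm = wl[ord],
    intensity = it[ord]
  )
  check_group_labels(out$group)
  validate_spectra(out, arg = path)
  out
}

#' Read a labelled spectra dataset via a manifest
#'
#' The manifest is a CSV with columns `spectrum_id,group,animal_id,file`;
#' `file` paths are resolved relative to the manifest's directory. Group
#' labels must be one of [fibrosis_groups()] (empty/`NA` allowed for
#' prediction-only sets). The returned tibble preserves manifest row order.
#'
#' @param manifest Path to the manifest CSV.
#' @return A long spectra tibble (see [read_spectrum()]) covering all files.
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest)) {
    stop(sprintf("manifest not found: %s", manifest), call. = FALSE)
  }
  man <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  required <- c("spectrum_id", "group", "animal_id", "file")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0) {
    stop(sprintf("manifest lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  man$group <- as.character(man$group)
  man$group[!is.na(man$group) & man$group == ""] <- NA_character_
  check_group_labels(man$group)
  base <- dirname(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$file), man$file,
                  file.path(base, man$file))
  gone <- which(!file.exists(paths))
  if (length(gone) > 0) {
    stop(sprintf("manifest row %d: file not found: %s", gone[[1]], man$file[gone[[1]]]),
         call. = FALSE)
  }
  purrr::pmap(
    list(paths, man$spectrum_id, man$group, as.character(man$animal_id)),
    function(p, id, g, a) read_spectrum(p, spectrum_id = id, group = g, animal_id = a)
  ) |>
    dplyr::bind_rows()
}

#' Write a spectra dataset as per-spectrum CSVs plus a manifest
#'
#' Inverse of [read_dataset()]: one `<spectrum_id>.csv` per spectrum
#' (`wavelength_nm,intensity` at full double precision, so a write-then-read
#' round trip is bit-stable) and a `manifest.csv`.
#'
#' @param spectra A long spectra tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(spectra, dir) {
  validate_spectra(spectra)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- spectra |>
    dplyr::distinct(.data$spectrum_id, .data$group, .data$animal_id) |>
    dplyr::mutate(file = paste0(.data$spectrum_id, ".csv"))
  purrr::walk(meta$spectrum_id, function(id) {
    spectra |>
      dplyr::filter(.data$spectrum_id == id) |>
      dplyr::select("wavelength_nm", "intensity") |>
      readr::write_csv(file.path(dir, paste0(id, ".csv")), progress = FALSE)
  })
  man_path <- file.path(dir, "manifest.csv")
  readr::write_csv(meta, man_path, progress = FALSE)
  invisible(man_path)
}

#' Write result tables and a run summary
#'
#' Writes whichever result tables are supplied as CSV files
#' (`peaks.csv`, `hemoglobin.csv`, `classification.csv`, `roc_points.csv`,
#' `discriminant_scores.csv`, `ellipses.csv`, `anova.csv`) plus a
#' `run_summary.json` recording the run configuration (including the seed).
#' Numeric values are written at full double precision.
#'
#' @param results Named list; recognised elements `peaks`, `hemoglobin`,
#'   `classification`, `roc_points`, `discriminant_scores`, `ellipses`,
#'   `anova` (tibbles) and `config` (list, serialised into the summary).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(is.list(results))
  ok <- tryCatch({
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  }
  tables <- c("peaks", "hemoglobin", "classification", "roc_points",
              "discriminant_scores", "ellipses", "anova")
  written <- character(0)
  for (nm in intersect(tables, names(results))) {
    tbl <- results[[nm]]
    if (is.null(tbl)) next
    # drop list-columns (e.g. embedded ROC point tables) for flat CSV output
    flat <- tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(flat, path, progress = FALSE)
    written <- c(written, path)
  }
  summary_path <- file.path(out_dir, "run_summary.json")
  summary <- list(
    package = "fluorostage",
    config = results$config %||% list(),
    tables = basename(written)
  )
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(written, summary_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
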