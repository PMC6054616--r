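#' One-way analysis of variance
#'
#' Classical one-way ANOVA of a numeric response across groups, returning
#' the F statistic, degrees of freedom and p-value from the F distribution,
#' with significance flags at the 0.05 and 0.005 levels. If the within-group
#' variance is exactly zero while group means differ, `F` is infinite and
#' `p = 0` is reported with `degenerate = TRUE` rather than an error.
#'
#' @param values Numeric response vector.
#' @param groups Group membership vector (same length).
#' @param variable Optional name recorded in the output.
#' @return One-row tibble: `variable`, `groups_compared`, `F`, `df_between`,
#'   `df_within`, `p_value`, `significant_005`, `significant_0005`,
#'   `degenerate`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
one_way_anova <- function(values, groups, variable = NA_character_) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop(sprintf("group '%s' has fewer than 2 values", names(sizes)[sizes < 2][[1]]),
         call. = FALSE)
  }
  k <- length(sizes)
  n <- length(values)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  means <- tapply(values, groups, mean)
  ssb <- sum(sizes * (means - mean(values))^2)
  degenerate <- ssw <= .Machine$double.eps * sum(values^2) && ssb > 0
  if (degenerate) {
    f <- Inf
    p <- 0
  } else {
    fit <- stats::anova(stats::lm(values ~ factor(groups)))
    f <- fit$`F value`[[1]]
    p <- fit$`Pr(>F)`[[1]]
  }
  tibble::tibble(
    variable = variable,
    groups_compared = paste(names(sizes), collapse = "-"),
    F = f,
    df_between = k - 1,
    df_within = n - k,
    p_value = p,
    significant_005 = p < 0.05,
    significant_0005 = p < 0.005,
    degenerate = degenerate
  )
}

#' Pairwise ANOVA significance table over fitted features
#'
#' Runs [one_way_anova()] for each lesion pair on each analysis variable:
#' fitted band intensity (amplitude) and band area for every band in
#' `bands`, plus the hemoglobin log-ratio index when supplied. No
#' multiple-testing correction is applied; both the 0.05 and 0.005 flags are
#' reported.
#'
#' @param peaks Peak-fit table from [fit_peaks_dataset()].
#' @param thc Optional hemoglobin index table from [thc_index()].
#' @param pairs List of group pairs (default [default_pairs()]).
#' @param bands Band names to test (default `"lipopigments"`).
#' @return Tibble with one row per variable x pair (row count
#'   `(2 * length(bands) + !is.null(thc)) * length(pairs)`).
#' @export
pairwise_significance_table <- function(peaks, thc = NULL,
                                        pairs = default_pairs(),
                                        bands = "lipopigments") {
  needed <- c("spectrum_id", "group", "band", "amplitude", "area")
  missing <- setdiff(needed, names(peaks))
  if (length(missing) > 0) {
    stop(sprintf("peaks table lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  vars <- list()
  for (b in bands) {
    sel <- peaks[peaks$band == b, ]
    if (nrow(sel) == 0) {
      stop(sprintf("band '%s' absent from peaks table", b), call. = FALSE)
    }
    vars[[paste0(b, "_intensity")]] <- sel[, c("group", "amplitude")] |>
      stats::setNames(c("group", "value"))
    vars[[paste0(b, "_area")]] <- sel[, c("group", "area")] |>
      stats::setNames(c("group", "value"))
  }
  if (!is.null(thc)) {
    if (!"log_ratio" %in% names(thc)) {
      stop("thc table lacks the log_ratio column", call. = FALSE)
    }
    vars[["thc_log_ratio"]] <- thc[, c("group", "log_ratio")] |>
      stats::setNames(c("group", "value"))
  }
  out <- list()
  for (vn in names(vars)) {
    v <- vars[[vn]]
    for (pair in pairs) {
      sel <- v[!is.na(v$group) & v$group %in% pair, ]
      out[[length(out) + 1]] <- one_way_anova(sel$value, sel$group, variable = vn)
    }
  }
  dplyr::bind_rows(out)
}
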