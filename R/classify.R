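# Internal: long spectra -> samples x wavelengths matrix plus metadata.
spectra_matrix <- function(spectra) {
  validate_spectra(spectra)
  common_grid(spectra)
  wide <- spectra |>
    dplyr::select("spectrum_id", "group", "wavelength_nm", "intensity") |>
    tidyr::pivot_wider(names_from = "wavelength_nm", values_from = "intensity")
  X <- as.matrix(wide[, -(1:2)])
  rownames(X) <- wide$spectrum_id
  list(X = X, spectrum_id = wide$spectrum_id, group = wide$group)
}

#' Principal component analysis of a spectra matrix
#'
#' Mean-centred PCA (no variance scaling) of the samples-by-wavelengths
#' matrix. Retains the smallest leading set of components whose cumulative
#' explained variance reaches `var_threshold`, with a floor of
#' `min_components`.
#'
#' @param spectra Long spectra tibble on a common grid (>= 2 spectra).
#' @param var_threshold Cumulative explained-variance threshold in (0, 1].
#' @param min_components Minimum number of retained components.
#' @return Object of class `spectral_pca`: `mean_spectrum`, `loadings`
#'   (retained components x wavelengths), `explained_variance_fractions`
#'   (all components), `n_retained`, `scores` (tibble with `spectrum_id`,
#'   `group`, `PC1..PCk`), `wavelength_nm`.
#' @export
fit_pca <- function(spectra, var_threshold = 0.95, min_components = 2) {
  m <- spectra_matrix(spectra)
  if (nrow(m$X) < 2) stop("PCA needs at least 2 spectra", call. = FALSE)
  pr <- stats::prcomp(m$X, center = TRUE, scale. = FALSE)
  total <- sum(pr$sdev^2)
  if (total < 1e-20) {
    stop("degenerate data: zero variance across spectra", call. = FALSE)
  }
  frac <- pr$sdev^2 / total
  n_retained <- max(min_components, which(cumsum(frac) >= var_threshold)[[1]])
  n_retained <- min(n_retained, ncol(pr$rotation))
  scores <- tibble::as_tibble(pr$x[, seq_len(n_retained), drop = FALSE])
  structure(
    list(
      mean_spectrum = pr$center,
      loadings = t(pr$rotation[, seq_len(n_retained), drop = FALSE]),
      explained_variance_fractions = frac,
      n_retained = n_retained,
      scores = dplyr::bind_cols(
        tibble::tibble(spectrum_id = m$spectrum_id, group = m$group), scores
      ),
      wavelength_nm = as.numeric(colnames(m$X))
    ),
    class = "spectral_pca"
  )
}

#' @export
print.spectral_pca <- function(x, ...) {
  cat(sprintf("<spectral_pca> %d retained components (%.1f%% variance) from %d spectra\n",
              x$n_retained,
              100 * sum(x$explained_variance_fractions[seq_len(x$n_retained)]),
              nrow(x$scores)))
  invisible(x)
}

#' Project new spectra onto a fitted PCA basis
#'
#' Uses only the training-derived mean spectrum and loadings — validation
#' data never refit the basis.
#'
#' @param pca A `spectral_pca` object.
#' @param spectra Long spectra tibble on the same grid.
#' @return Score tibble (`spectrum_id`, `group`, `PC1..PCk`).
#' @export
project_pca <- function(pca, spectra) {
  m <- spectra_matrix(spectra)
  if (!identical(as.numeric(colnames(m$X)), pca$wavelength_nm)) {
    stop("spectra are not on the PCA training grid", call. = FALSE)
  }
  scores <- sweep(m$X, 2, pca$mean_spectrum) %*% t(pca$loadings)
  colnames(scores) <- paste0("PC", seq_len(pca$n_retained))
  dplyr::bind_cols(
    tibble::tibble(spectrum_id = m$spectrum_id, group = m$group),
    tibble::as_tibble(scores)
  )
}

#' Split a labelled dataset into training and validation sets
#'
#' Random split without replacement, per group, seeded: `n_train` training
#' and `n_valid` validation spectra from each group.
#'
#' @param spectra Long spectra tibble.
#' @param n_train,n_valid Spectra per group in each role.
#' @param seed Integer seed for the draw.
#' @return The input tibble with an added `role` column
#'   (`"training"`/`"validation"`); spectra not drawn are dropped.
#' @export
split_train_validation <- function(spectra, n_train = 50, n_valid = 10, seed = 1) {
  meta <- spectra |>
    dplyr::distinct(.data$spectrum_id, .data$group) |>
    dplyr::filter(!is.na(.data$group))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  roles <- meta |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < n_train + n_valid) {
        stop(sprintf("group '%s' has %d spectra; %d needed for the %d/%d split",
                     key$group, nrow(d), n_train + n_valid, n_train, n_valid),
             call. = FALSE)
      }
      picked <- sample(d$spectrum_id, n_train + n_valid)
      tibble::tibble(
        spectrum_id = picked,
        role = rep(c("training", "validation"), c(n_train, n_valid))
      )
    }) |>
    dplyr::ungroup()
  spectra |>
    dplyr::inner_join(roles, by = c("spectrum_id", "group"))
}

#' Fisher linear discriminant for one lesion pair
#'
#' Computes the Fisher direction `w = Sw^-1 (m_pos - m_neg)` on PC scores
#' for two groups, with scores shifted so the midpoint of the two class mean
#' scores is 0 and the positive class (by default the more advanced lesion
#' of the pair) lies on the positive side. The decision cutoff is 0.
#'
#' @param scores Score tibble (`group` plus `PC*` columns), restricted or
#'   restrictable to the two groups of `pair`.
#' @param pair Character vector of two group labels.
#' @param positive Positive class; defaults to the more advanced stage
#'   (severity order control < reversal < mild < moderate).
#' @return Object of class `pairwise_lda`: `pair`, `positive`, `negative`,
#'   `weights`, `offset`, `cutoff`, `training_scores` (tibble with
#'   discriminant `score` per training spectrum).
#' @export
fit_lda_pairwise <- function(scores, pair, positive = NULL) {
  stopifnot(length(pair) == 2)
  check_group_labels(pair)
  if (is.null(positive)) {
    sev <- stage_severity()
    positive <- pair[[which.max(sev[pair])]]
  }
  stopifnot(positive %in% pair)
  negative <- setdiff(pair, positive)
  pc_cols <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  if (length(pc_cols) == 0) stop("no PC score columns found", call. = FALSE)
  d <- scores[!is.na(scores$group) & scores$group %in% pair, ]
  if (!all(pair %in% d$group)) {
    stop("both classes of the pair must be present", call. = FALSE)
  }
  X <- as.matrix(d[, pc_cols])
  g <- d$group
  if (min(table(g)) < 2) stop("each class needs >= 2 members", call. = FALSE)
  m_pos <- colMeans(X[g == positive, , drop = FALSE])
  m_neg <- colMeans(X[g == negative, , drop = FALSE])
  # Pooled within-class scatter
  Sw <- matrix(0, length(pc_cols), length(pc_cols))
  for (cl in pair) {
    Xc <- scale(X[g == cl, , drop = FALSE], scale = FALSE)
    Sw <- Sw + crossprod(Xc)
  }
  w <- tryCatch(
    solve(Sw, m_pos - m_neg),
    error = function(e) {
      warning("singular within-class scatter; using ridge-regularised inverse",
              call. = FALSE)
      solve(Sw + diag(1e-8 * mean(diag(Sw)) + 1e-12, nrow(Sw)), m_pos - m_neg)
    }
  )
  offset <- -sum(w * (m_pos + m_neg) / 2)
  model <- structure(
    list(pair = pair, positive = positive, negative = negative,
         weights = stats::setNames(w, pc_cols), offset = offset, cutoff = 0),
    class = "pairwise_lda"
  )
  model$training_scores <- discriminant_scores(model, d)
  model
}

#' @export
print.pairwise_lda <- function(x, ...) {
  cat(sprintf("<pairwise_lda> %s vs %s (positive: %s), cutoff 0, %d PCs\n",
              x$pair[[1]], x$pair[[2]], x$positive, length(x$weights)))
  invisible(x)
}

#' Discriminant scores of spectra under a pairwise LDA model
#'
#' @param model A `pairwise_lda` object.
#' @param scores Score tibble with the model's PC columns.
#' @return Tibble `spectrum_id`, `group`, `score`.
#' @export
discriminant_scores <- function(model, scores) {
  pc_cols <- names(model$weights)
  missing <- setdiff(pc_cols, names(scores))
  if (length(missing) > 0) {
    stop(sprintf("scores lack column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(
    spectrum_id = scores$spectrum_id,
    group = scores$group,
    score = as.numeric(as.matrix(scores[, pc_cols]) %*% model$weights + model$offset)
  )
}

#' Sensitivity/specificity report for one lesion pair
#'
#' Classifies by the sign of the discriminant score at cutoff 0 (score >= 0
#' is called positive) and tabulates the confusion counts; also sweeps the
#' threshold to attach the ROC curve and AUC for the same scores.
#'
#' @param model A `pairwise_lda` object.
#' @param scores Score tibble (PC columns) with labels restricted to the
#'   model's pair.
#' @param role Label recorded in the report (`"training"`, `"validation"` or
#'   `"overall"`).
#' @return One-row tibble of class `classification_report`: `pair`, `role`,
#'   `positive`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`
#'   (percent), `auc`, and a `roc` list-column holding the ROC points.
#' @export
evaluate_pair <- function(model, scores,
                          role = c("validation", "training", "overall")) {
  role <- match.arg(role)
  outside <- setdiff(unique(scores$group), model$pair)
  if (length(outside) > 0) {
    stop(sprintf("labels outside the model's pair: %s",
                 paste(outside, collapse = ", ")), call. = FALSE)
  }
  ds <- discriminant_scores(model, scores)
  truth_pos <- ds$group == model$positive
  called_pos <- ds$score >= model$cutoff
  tp <- sum(truth_pos & called_pos)
  fn <- sum(truth_pos & !called_pos)
  tn <- sum(!truth_pos & !called_pos)
  fp <- sum(!truth_pos & called_pos)
  roc <- roc_curve(ds$score, truth_pos)
  out <- tibble::tibble(
    pair = paste(model$negative, model$positive, sep = "-"),
    role = role,
    positive = model$positive,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    auc = roc$auc,
    roc = list(roc$points)
  )
  class(out) <- c("classification_report", class(out))
  out
}

#' ROC curve by exhaustive threshold sweep
#'
#' Sweeps the decision threshold over all distinct score values and returns
#' the (FPR, TPR) staircase with endpoints (0,0) and (1,1), plus the
#' trapezoidal area under the curve. With ties handled by the trapezoid,
#' the AUC equals the Mann-Whitney statistic (ties counted 1/2).
#'
#' @param scores Numeric discriminant scores.
#' @param labels Logical (or coercible) vector, `TRUE` for the positive
#'   class.
#' @return List with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at the end of each tie-block of distinct score values
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[block_end]
  fp <- cumsum(!l)[block_end]
  points <- tibble::tibble(
    threshold = c(Inf, s[block_end]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Multiclass discriminant projection with 2-SD confidence ellipses
#'
#' Fisher multiclass LDA of the full dataset's PC scores to two discriminant
#' dimensions (leading eigenvectors of `Sw^-1 Sb`), followed by per-class
#' centroids, 2x2 covariance matrices, two-standard-deviation ellipses
#' (semi-axes `2 sqrt(eigenvalues)`), per-spectrum inside-own-ellipse flags
#' (Mahalanobis distance <= 2), and a nearest-centroid confusion matrix.
#'
#' @param scores Score tibble (`spectrum_id`, `group`, `PC*`) for all
#'   labelled spectra; every group needs >= 3 members.
#' @return Object of class `ellipse_summary`: `coords` (tibble with `ld1`,
#'   `ld2`, `mahalanobis`, `inside_own`, `assigned`), `ellipses` (tibble with
#'   centroid, covariance entries, semi-axes, orientation and inside/outside
#'   counts) and `confusion` (tibble `group` x `assigned` counts).
#' @export
confusion_ellipse_analysis <- function(scores) {
  pc_cols <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  d <- scores[!is.na(scores$group), ]
  groups <- sort(unique(d$group))
  sizes <- table(d$group)
  if (any(sizes < 3)) {
    stop("every class needs >= 3 members for covariance estimation", call. = FALSE)
  }
  X <- as.matrix(d[, pc_cols])
  g <- d$group
  gm <- colMeans(X)
  Sw <- matrix(0, ncol(X), ncol(X))
  Sb <- matrix(0, ncol(X), ncol(X))
  for (cl in groups) {
    Xc <- X[g == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    Sw <- Sw + crossprod(scale(Xc, scale = FALSE))
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - gm)
  }
  ev <- eigen(solve(Sw + diag(1e-12, nrow(Sw)), Sb))
  W <- Re(ev$vectors[, 1:2, drop = FALSE])
  Z <- X %*% W
  colnames(Z) <- c("ld1", "ld2")
  coords <- dplyr::bind_cols(
    tibble::tibble(spectrum_id = d$spectrum_id, group = g),
    tibble::as_tibble(Z)
  )
  cents <- coords |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(cx = mean(.data$ld1), cy = mean(.data$ld2), .groups = "drop")
  ellipses <- purrr::map(groups, function(cl) {
    Zc <- Z[g == cl, , drop = FALSE]
    ctr <- colMeans(Zc)
    S <- stats::cov(Zc)
    es <- eigen(S, symmetric = TRUE)
    ang <- atan2(es$vectors[2, 1], es$vectors[1, 1])
    md <- sqrt(stats::mahalanobis(Zc, ctr, S))
    tibble::tibble(
      group = cl, cx = ctr[[1]], cy = ctr[[2]],
      var_ld1 = S[1, 1], var_ld2 = S[2, 2], cov_ld12 = S[1, 2],
      semi_axis_1 = 2 * sqrt(es$values[[1]]), semi_axis_2 = 2 * sqrt(es$values[[2]]),
      angle_rad = ang,
      n_inside = sum(md <= 2), n_outside = sum(md > 2)
    )
  }) |> dplyr::bind_rows()
  # per-spectrum: Mahalanobis to own class, nearest-centroid assignment
  own_md <- numeric(nrow(coords))
  for (cl in groups) {
    idx <- which(g == cl)
    Zc <- Z[idx, , drop = FALSE]
    own_md[idx] <- sqrt(stats::mahalanobis(Zc, colMeans(Zc), stats::cov(Zc)))
  }
  cent_mat <- as.matrix(cents[, c("cx", "cy")])
  d2 <- outer(rowSums(Z^2), rep(1, nrow(cent_mat))) -
    2 * Z %*% t(cent_mat) + outer(rep(1, nrow(Z)), rowSums(cent_mat^2))
  coords$mahalanobis <- own_md
  coords$inside_own <- own_md <= 2
  coords$assigned <- cents$group[max.col(-d2)]
  confusion <- coords |>
    dplyr::count(.data$group, .data$assigned) |>
    tidyr::pivot_wider(names_from = "assigned", values_from = "n", values_fill = 0)
  structure(
    list(coords = coords, ellipses = ellipses, confusion = confusion),
    class = "ellipse_summary"
  )
}

#' @export
print.ellipse_summary <- function(x, ...) {
  cat("<ellipse_summary>\n")
  print(x$ellipses)
  cat("nearest-centroid confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}

#' Default lesion pairs for pairwise classification
#'
#' @return List of character pairs: control-mild, mild-moderate,
#'   moderate-reversal, mild-reversal.
#' @export
default_pairs <- function() {
  list(
    c("control", "mild"),
    c("mild", "moderate"),
    c("moderate", "reversal"),
    c("mild", "reversal")
  )
}

#' Pairwise PCA-LDA staging classification
#'
#' The full multivariate workflow: a seeded per-group training/validation
#' split (default 50/10), PCA of the pooled training spectra, a Fisher
#' discriminant with cutoff 0 per lesion pair, training and validation
#' reports (validation spectra are projected through the training PCA and
#' weights, never refit), a pooled-score ROC per pair, and the full-dataset
#' confusion-ellipse analysis.
#'
#' @param spectra Normalized spectra tibble on the standard grid.
#' @param n_train,n_valid Per-group training/validation sizes.
#' @param seed Seed for the split.
#' @param var_threshold Cumulative variance retained by the PCA.
#' @param pairs List of group pairs (default [default_pairs()]).
#' @param roc_on Which scores feed the headline per-pair ROC:
#'   `"overall"` (pooled training+validation, default), `"training"` or
#'   `"validation"`.
#' @return Object of class `staging_classification`: `pca`, `models` (named
#'   list of `pairwise_lda`), `reports` (stacked classification reports,
#'   roles training/validation/overall per pair), `scores` (discriminant
#'   scores with roles), `ellipse` (full-data [confusion_ellipse_analysis()]),
#'   `split` (spectrum_id/group/role), `config`.
#' @export
classify_pairs <- function(spectra, n_train = 50, n_valid = 10, seed = 1,
                           var_threshold = 0.95, pairs = default_pairs(),
                           roc_on = c("overall", "training", "validation")) {
  roc_on <- match.arg(roc_on)
  labelled <- split_train_validation(spectra, n_train, n_valid, seed)
  train <- labelled[labelled$role == "training", ]
  valid <- labelled[labelled$role == "validation", ]
  pca <- fit_pca(train, var_threshold = var_threshold)
  train_scores <- pca$scores
  valid_scores <- project_pca(pca, valid)
  models <- list()
  reports <- list()
  all_scores <- list()
  for (pair in pairs) {
    key <- paste(pair, collapse = "-")
    tr <- train_scores[train_scores$group %in% pair, ]
    va <- valid_scores[valid_scores$group %in% pair, ]
    model <- fit_lda_pairwise(tr, pair)
    models[[key]] <- model
    rep_tr <- evaluate_pair(model, tr, role = "training")
    rep_va <- evaluate_pair(model, va, role = "validation")
    rep_all <- evaluate_pair(model, dplyr::bind_rows(tr, va), role = "overall")
    reports[[key]] <- dplyr::bind_rows(rep_tr, rep_va, rep_all)
    sc <- dplyr::bind_rows(
      dplyr::mutate(discriminant_scores(model, tr), role = "training"),
      dplyr::mutate(discriminant_scores(model, va), role = "validation")
    )
    sc$pair <- key
    all_scores[[key]] <- sc
  }
  reports <- dplyr::bind_rows(reports)
  full_scores <- dplyr::bind_rows(
    train_scores,
    valid_scores
  )
  structure(
    list(
      pca = pca,
      models = models,
      reports = reports,
      scores = dplyr::bind_rows(all_scores),
      ellipse = confusion_ellipse_analysis(full_scores),
      split = dplyr::distinct(labelled, .data$spectrum_id, .data$group, .data$role),
      config = list(n_train = n_train, n_valid = n_valid, seed = seed,
                    var_threshold = var_threshold, roc_on = roc_on)
    ),
    class = "staging_classification"
  )
}

#' @export
print.staging_classification <- function(x, ...) {
  cat(sprintf("<staging_classification> %d PCs, %d pairs\n",
              x$pca$n_retained, length(x$models)))
  print(dplyr::select(x$reports, -"roc"))
  invisible(x)
}
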