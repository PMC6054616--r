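# score-tibble fixture: 2-D PC scores for two or more groups
make_scores <- function(..., prefix = "s") {
  groups <- list(...)
  purrr::imap(groups, function(m, g) {
    tibble::tibble(
      spectrum_id = sprintf("%s_%s_%d", prefix, g, seq_len(nrow(m))),
      group = g, PC1 = m[, 1], PC2 = m[, 2]
    )
  }) |> dplyr::bind_rows()
}

test_that("fit_pca retains variance and reconstructs the data", {
  d <- normalize_spectra(generate_dataset(n_per_group = 3, seed = 19))
  pca <- fit_pca(d, var_threshold = 1, min_components = 2)
  # full-rank reconstruction reproduces the centered data
  m <- d |>
    dplyr::select(spectrum_id, wavelength_nm, intensity) |>
    tidyr::pivot_wider(names_from = wavelength_nm, values_from = intensity)
  X <- as.matrix(m[, -1])
  S <- as.matrix(pca$scores[, -(1:2)])
  recon <- S %*% pca$loadings + matrix(pca$mean_spectrum, nrow(X), ncol(X), byrow = TRUE)
  expect_lt(max(abs(recon - X)), 1e-9)
  # loadings rows orthonormal
  G <- pca$loadings %*% t(pca$loadings)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-9)
  # explained variance fractions nonincreasing in (0, 1]
  ev <- pca$explained_variance_fractions
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(all(ev > 0 & ev <= 1))
  expect_gte(pca$n_retained, 2)
})

test_that("fit_pca flags degenerate inputs", {
  same <- spectra_tbl(list(a = rep(1, 310), b = rep(1, 310)), group = "control")
  expect_error(fit_pca(same), "degenerate")
  one <- spectra_tbl(list(a = rep(1, 310)))
  expect_error(fit_pca(one), "at least 2")
})

test_that("near-collinear data concentrate variance on the first component", {
  set.seed(4)
  t <- seq(0, 1, length.out = 30)
  ys <- purrr::map(t, function(k) 0.5 + k * seq(0, 1, length.out = 310) +
                     stats::rnorm(310, 0, 1e-4))
  names(ys) <- sprintf("s%02d", seq_along(ys))
  pca <- fit_pca(spectra_tbl(ys))
  expect_gt(pca$explained_variance_fractions[[1]], 0.99)
})

test_that("projection through a fitted PCA uses only training statistics", {
  d <- default_dataset()
  split <- split_train_validation(d, n_train = 50, n_valid = 10, seed = 17)
  train <- split[split$role == "training", ]
  valid <- split[split$role == "validation", ]
  pca <- fit_pca(train)
  # training projection equals prcomp's own scores
  expect_equal(as.matrix(project_pca(pca, train)[, -(1:2)]),
               as.matrix(pca$scores[, -(1:2)]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # shuffling validation spectra permutes scores but changes nothing else
  ids <- unique(valid$spectrum_id)
  shuffled <- valid |>
    dplyr::mutate(spectrum_id = factor(spectrum_id, levels = rev(ids))) |>
    dplyr::arrange(spectrum_id) |>
    dplyr::mutate(spectrum_id = as.character(spectrum_id))
  a <- project_pca(pca, valid)
  b <- project_pca(pca, shuffled)
  expect_equal(
    dplyr::arrange(a, spectrum_id),
    dplyr::arrange(b, spectrum_id),
    tolerance = 1e-12
  )
})

test_that("the Fisher discriminant centers class means symmetrically about 0", {
  set.seed(8)
  a <- cbind(stats::rnorm(20, -5, 0.1), stats::rnorm(20, 0, 0.1))
  b <- cbind(stats::rnorm(20, 5, 0.1), stats::rnorm(20, 0, 0.1))
  scores <- make_scores(control = a, moderate = b)
  model <- fit_lda_pairwise(scores, c("control", "moderate"))
  expect_equal(model$positive, "moderate")
  ds <- model$training_scores
  m_pos <- mean(ds$score[ds$group == "moderate"])
  m_neg <- mean(ds$score[ds$group == "control"])
  expect_lt(abs(m_pos + m_neg), 1e-9)
  expect_gt(m_pos, 0)
  # well separated clusters classify perfectly at cutoff 0
  rep <- evaluate_pair(model, scores, role = "training")
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100)
})

test_that("swapping the positive class negates the discriminant", {
  set.seed(9)
  a <- cbind(stats::rnorm(15, -1), stats::rnorm(15, 0.5))
  b <- cbind(stats::rnorm(15, 1), stats::rnorm(15, -0.5))
  scores <- make_scores(mild = a, moderate = b)
  m1 <- fit_lda_pairwise(scores, c("mild", "moderate"), positive = "moderate")
  m2 <- fit_lda_pairwise(scores, c("mild", "moderate"), positive = "mild")
  expect_equal(unname(m1$weights), -unname(m2$weights), tolerance = 1e-9)
  r1 <- evaluate_pair(m1, scores, role = "training")
  r2 <- evaluate_pair(m2, scores, role = "training")
  expect_equal(r1$sensitivity, r2$specificity)
  expect_equal(r1$specificity, r2$sensitivity)
})

test_that("the Fisher direction matches a brute-force angle scan", {
  set.seed(10)
  a <- cbind(stats::rnorm(40, 0, 1), stats::rnorm(40, 0, 0.3))
  a <- a %*% matrix(c(cos(0.6), sin(0.6), -sin(0.6), cos(0.6)), 2)
  b <- sweep(a[1:35, ], 2, c(1.5, 1.0), "+")
  scores <- make_scores(control = a, mild = b)
  model <- fit_lda_pairwise(scores, c("control", "mild"))

  X <- as.matrix(scores[, c("PC1", "PC2")])
  g <- scores$group
  m_diff <- colMeans(X[g == "mild", ]) - colMeans(X[g == "control", ])
  Sw <- crossprod(scale(X[g == "mild", ], scale = FALSE)) +
    crossprod(scale(X[g == "control", ], scale = FALSE))
  angles <- seq(0, pi, by = pi / 3600)
  J <- purrr::map_dbl(angles, function(th) {
    w <- c(cos(th), sin(th))
    (sum(w * m_diff))^2 / drop(t(w) %*% Sw %*% w)
  })
  best <- angles[which.max(J)]
  got <- atan2(model$weights[[2]], model$weights[[1]]) %% pi
  expect_lt(min(abs(got - best), pi - abs(got - best)), 0.5 * pi / 180)

  # and agrees with MASS's LDA direction up to scale
  ml <- MASS::lda(X, grouping = g)
  cosine <- sum(ml$scaling * model$weights) /
    sqrt(sum(ml$scaling^2) * sum(model$weights^2))
  expect_gt(abs(cosine), 1 - 1e-8)
})

test_that("evaluate_pair tabulates confusion counts correctly", {
  # 10 + 10 validation set with 2 positives and 1 negative misclassified:
  # sensitivity 80%, specificity 90%
  model <- structure(
    list(pair = c("reversal", "mild"), positive = "mild", negative = "reversal",
         weights = c(PC1 = 1), offset = 0, cutoff = 0),
    class = "pairwise_lda"
  )
  scores <- tibble::tibble(
    spectrum_id = sprintf("v%02d", 1:20),
    group = rep(c("mild", "reversal"), each = 10),
    PC1 = c(rep(1, 8), -1, -1, rep(-1, 9), 1)
  )
  rep <- evaluate_pair(model, scores, role = "validation")
  expect_equal(rep$tp, 8)
  expect_equal(rep$fn, 2)
  expect_equal(rep$tn, 9)
  expect_equal(rep$fp, 1)
  expect_equal(rep$sensitivity, 80)
  expect_equal(rep$specificity, 90)

  expect_error(
    evaluate_pair(model, dplyr::mutate(scores, group = replace(group, 1, "control"))),
    "outside"
  )

  # brute-force recount on random scores agrees
  set.seed(12)
  rnd <- tibble::tibble(
    spectrum_id = sprintf("r%02d", 1:30),
    group = sample(c("mild", "reversal"), 30, replace = TRUE, prob = c(0.5, 0.5)),
    PC1 = stats::rnorm(30)
  )
  rnd$group[1:2] <- c("mild", "reversal") # both classes present
  r <- evaluate_pair(model, rnd, role = "overall")
  pos <- rnd$group == "mild"
  called <- rnd$PC1 >= 0
  expect_equal(r$tp, sum(pos & called))
  expect_equal(r$fp, sum(!pos & called))
  expect_equal(r$tn, sum(!pos & !called))
  expect_equal(r$fn, sum(pos & !called))
  expect_equal(r$sensitivity, 100 * r$tp / (r$tp + r$fn))
})

test_that("roc_curve sweeps thresholds and equals the Mann-Whitney statistic", {
  perfect <- roc_curve(c(1, 2, 3, -1, -2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$points$fpr[[1]], 0)
  expect_equal(perfect$points$tpr[[1]], 0)
  expect_equal(dplyr::last(perfect$points$fpr), 1)
  expect_equal(dplyr::last(perfect$points$tpr), 1)

  # exhaustive pair-count oracle, including ties
  set.seed(14)
  scores <- sample(round(stats::rnorm(60), 1)) # rounding forces ties
  labels <- stats::runif(60) < 0.4
  labels[1:2] <- c(TRUE, FALSE)
  r <- roc_curve(scores, labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  expect_equal(r$auc, mean(pairs), tolerance = 1e-12)
  # monotone staircase
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # agrees with pROC
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)

  # invariance under strictly increasing transforms
  r2 <- roc_curve(exp(scores), labels)
  r3 <- roc_curve(2 * scores + 3, labels)
  expect_equal(r2$auc, r$auc)
  expect_equal(r3$auc, r$auc)

  # labels independent of scores: AUC near 1/2
  set.seed(15)
  null_scores <- stats::rnorm(600)
  null_labels <- rep(c(TRUE, FALSE), 300)
  expect_equal(roc_curve(null_scores, null_labels)$auc, 0.5, tolerance = 0.07)

  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("confusion_ellipse_analysis separates tight distant clusters", {
  set.seed(16)
  centers <- list(control = c(0, 0), mild = c(20, 0),
                  moderate = c(0, 20), reversal = c(20, 20))
  scores <- purrr::imap(centers, function(ctr, g) {
    tibble::tibble(
      spectrum_id = sprintf("%s_%d", g, 1:15), group = g,
      PC1 = stats::rnorm(15, ctr[1], 0.3), PC2 = stats::rnorm(15, ctr[2], 0.3),
      PC3 = stats::rnorm(15, 0, 0.3)
    )
  }) |> dplyr::bind_rows()
  ea <- confusion_ellipse_analysis(scores)
  expect_true(all(ea$coords$assigned == ea$coords$group))
  conf <- ea$confusion
  diag_counts <- purrr::map_int(conf$group, function(g) conf[[g]][conf$group == g])
  expect_true(all(diag_counts == 15))

  # centroid equals the member mean in the discriminant plane
  ctr_check <- ea$coords |>
    dplyr::group_by(group) |>
    dplyr::summarise(cx = mean(ld1), cy = mean(ld2), .groups = "drop")
  expect_equal(ea$ellipses$cx, ctr_check$cx, tolerance = 1e-9)
  expect_equal(ea$ellipses$cy, ctr_check$cy, tolerance = 1e-9)

  # inside-own-ellipse flag equals the direct Mahalanobis <= 2 rule
  for (g in names(centers)) {
    Z <- as.matrix(ea$coords[ea$coords$group == g, c("ld1", "ld2")])
    md <- sqrt(stats::mahalanobis(Z, colMeans(Z), stats::cov(Z)))
    expect_equal(ea$coords$inside_own[ea$coords$group == g], md <= 2)
  }
  # 2-SD semi-axes come from the covariance eigenvalues
  S <- stats::cov(as.matrix(ea$coords[ea$coords$group == "control", c("ld1", "ld2")]))
  expect_equal(ea$ellipses$semi_axis_1[ea$ellipses$group == "control"],
               2 * sqrt(eigen(S)$values[[1]]), tolerance = 1e-9)

  few <- dplyr::filter(scores, !(group == "mild" & spectrum_id != "mild_1"))
  expect_error(confusion_ellipse_analysis(few), ">= 3")
})

test_that("classify_pairs is reproducible and leak-free end to end", {
  d <- normalize_spectra(generate_dataset(n_per_group = 12, seed = 29))
  a <- classify_pairs(d, n_train = 8, n_valid = 4, seed = 3)
  b <- classify_pairs(d, n_train = 8, n_valid = 4, seed = 3)
  expect_equal(a$reports, b$reports)
  expect_identical(a$split, b$split)
  # the split respects the requested design
  expect_equal(
    dplyr::count(a$split, group, role)$n,
    rep(c(8, 4), 4)
  )
  # four pairs x three roles
  expect_equal(nrow(a$reports), 12)
  expect_setequal(unique(a$reports$role), c("training", "validation", "overall"))
})
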