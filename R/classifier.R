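# Per-view linear SVM with calibrated class scores.
#
# The fusion rule compares scores ACROSS two different classifiers, and raw
# SVM margins are not on a common scale, so each classifier carries a
# monotone margin -> probability map (Platt sigmoid fitted on out-of-sample
# margins from an internal stratified split of the training data). A
# `score_mode = "margin"` switch replaces the fitted sigmoid with a fixed
# unit-slope logistic squashing of the raw margin, for sensitivity analysis.

#' Train a linear SVM classifier on one feature view
#'
#' Fits, in order: a per-feature standardizer (center/scale) on the training
#' rows only; a linear-kernel SVM on the standardized features (positive
#' margin = presence class P); and a Platt-style sigmoid calibration mapping
#' the signed margin to `P(P | margin)`, fitted on out-of-sample margins
#' from an internal seeded stratified 3-fold split of the training data.
#' Calibrated scores are complementary (`score_P + score_A = 1`) and
#' strictly increasing in the margin.
#'
#' @param view A [feature_view()] of the training samples.
#' @param labels Character/factor vector of `"P"`/`"A"`, aligned with the
#'   view rows (or named by sample id).
#' @param cost SVM regularization constant C (default 1).
#' @param seed Integer seed for the internal calibration split.
#' @param score_mode `"platt"` (default, fitted sigmoid) or `"margin"`
#'   (fixed unit-slope logistic on the raw margin).
#' @return An object of class `view_classifier` with the fitted weight
#'   vector, bias, standardizer, calibration parameters, and config.
#' @export
train_view_classifier <- function(view, labels, cost = 1, seed = 1,
                                  score_mode = c("platt", "margin")) {
  stopifnot(inherits(view, "feature_view"))
  score_mode <- match.arg(score_mode)
  labels <- as_PA(labels, view$sample_ids)
  n_by <- table(factor(labels, levels = c("P", "A")))
  if (any(n_by < 2)) {
    stop_input("need at least 2 training samples of each class; got P=",
               n_by[["P"]], ", A=", n_by[["A"]])
  }
  std <- fit_standardizer(view$matrix)
  fit <- fit_linear_svm(apply_standardizer(std, view$matrix), labels, cost)

  calib <- if (score_mode == "platt") {
    fit_platt_calibration(view$matrix, labels, cost, seed)
  } else {
    list(intercept = 0, slope = 1)
  }

  structure(list(
    view_name = view$view_name,
    weights = fit$w,
    bias = fit$b,
    standardizer = std,
    calibration = calib,
    cost = cost,
    seed = as.integer(seed),
    score_mode = score_mode,
    n_train = nrow(view$matrix)
  ), class = "view_classifier")
}

as_PA <- function(labels, sample_ids = NULL) {
  labels <- as.character(labels)
  if (!is.null(names(labels)) && !is.null(sample_ids)) {
    if (!all(sample_ids %in% names(labels))) {
      stop_input("labels are named but do not cover all view sample ids")
    }
    labels <- labels[sample_ids]
  }
  if (!all(labels %in% c("P", "A"))) {
    stop_input("labels must be 'P' or 'A'; got: ",
               paste(unique(setdiff(labels, c("P", "A"))), collapse = ", "))
  }
  unname(labels)
}

# Per-feature center/scale. Zero-variance features keep scale 1 so they pass
# through centered but unscaled rather than erroring.
fit_standardizer <- function(mat) {
  center <- colMeans(mat)
  scale <- apply(mat, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, mat) {
  sweep(sweep(mat, 2, std$center, "-"), 2, std$scale, "/")
}

# Linear SVM via e1071; returns the explicit hyperplane (w, b) with the
# sign convention margin > 0 => class P.
fit_linear_svm <- function(x, labels, cost) {
  y <- factor(labels, levels = c("P", "A"))
  model <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                      scale = FALSE)
  w <- as.vector(crossprod(model$SV, model$coefs))
  b <- -model$rho
  # e1071's decision values are positive for the first factor level seen in
  # the data; verify against the reported ordering and flip if needed.
  dv <- attr(stats::predict(model, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  if (colnames(dv)[1] == "A/P") {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

raw_margin <- function(clf, mat) {
  as.vector(apply_standardizer(clf$standardizer, mat) %*% clf$weights + clf$bias)
}

# Platt calibration on out-of-sample margins: internal stratified k-fold
# (k = 3, reduced to 2 when a class has only 2 members) refits the
# standardizer + SVM per fold so calibration margins never come from rows
# the SVM was fitted on. Targets use Platt's smoothing
# t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2), which keeps the logistic fit
# finite on separable data. The slope is clamped to a small positive floor
# so the margin -> score map is strictly increasing even in degenerate
# (signal-free) fits.
fit_platt_calibration <- function(mat, labels, cost, seed) {
  k <- min(3L, min(table(labels)))
  folds <- stratified_folds(labels, k = k, seed = derive_seed(seed, 7901))
  margins <- numeric(length(labels))
  for (f in seq_len(k)) {
    tr <- folds != f
    std_f <- fit_standardizer(mat[tr, , drop = FALSE])
    fit_f <- fit_linear_svm(apply_standardizer(std_f, mat[tr, , drop = FALSE]),
                            labels[tr], cost)
    margins[!tr] <- as.vector(
      apply_standardizer(std_f, mat[!tr, , drop = FALSE]) %*% fit_f$w + fit_f$b)
  }
  n_pos <- sum(labels == "P")
  n_neg <- sum(labels == "A")
  target <- ifelse(labels == "P", (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  fit <- suppressWarnings(
    stats::glm(target ~ margins, family = stats::binomial())
  )
  co <- stats::coef(fit)
  slope <- max(co[["margins"]], 1e-8)
  list(intercept = unname(co[[1]]), slope = slope)
}

#' Predict calibrated class scores for a feature view
#'
#' Deterministic: computes signed margins under the stored hyperplane and
#' maps them through the stored monotone calibration. The label is `P` when
#' `score_P >= 0.5` (the tie at exactly 0.5 goes to P, favoring sensitivity:
#' a missed dysplastic lesion is the costlier error).
#'
#' @param object A `view_classifier`.
#' @param view A [feature_view()] with the same feature dimension.
#' @param ... Unused.
#' @return An object of class `classifier_output`: a `data.frame` with
#'   columns `sample_id`, `label`, `score_P`, `score_A`, `margin`.
#' @export
predict.view_classifier <- function(object, view, ...) {
  stopifnot(inherits(view, "feature_view"))
  if (ncol(view$matrix) != length(object$weights)) {
    stop_input("feature dimension mismatch: classifier has ",
               length(object$weights), ", view has ", ncol(view$matrix))
  }
  m <- raw_margin(object, view$matrix)
  score_P <- stats::plogis(object$calibration$intercept +
                             object$calibration$slope * m)
  classifier_output(view$sample_ids, score_P, margin = m)
}

#' Construct a classifier output
#'
#' @param sample_ids Sample ids, in prediction order.
#' @param score_P Calibrated presence scores in `[0, 1]`.
#' @param margin Optional raw signed margins.
#' @return A `classifier_output` data frame; `label` is `"P"` iff
#'   `score_P >= 0.5` and `score_A = 1 - score_P` elementwise.
#' @export
classifier_output <- function(sample_ids, score_P, margin = NA_real_) {
  if (any(score_P < 0 | score_P > 1)) stop_input("score_P must lie in [0, 1]")
  structure(data.frame(
    sample_id = as.character(sample_ids),
    label = ifelse(score_P >= 0.5, "P", "A"),
    score_P = score_P,
    score_A = 1 - score_P,
    margin = margin,
    stringsAsFactors = FALSE
  ), class = c("classifier_output", "data.frame"))
}

#' @export
print.view_classifier <- function(x, ...) {
  cat(sprintf("Linear SVM on view '%s': %d features, cost %g, %s scores\n",
              x$view_name, length(x$weights), x$cost, x$score_mode))
  cat(sprintf("Calibration: score_P = plogis(%.4g + %.4g * margin)\n",
              x$calibration$intercept, x$calibration$slope))
  invisible(x)
}

#' Serialize a trained view classifier to JSON
#'
#' Writes a self-describing text artifact (weights, bias, standardizer,
#' calibration, seed and config) that [read_view_classifier()] restores
#' exactly.
#'
#' @param clf A `view_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_view_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "view_classifier"))
  jsonlite::write_json(unclass(clf), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a view classifier written by [write_view_classifier()]
#'
#' @param path Path to the JSON artifact.
#' @return A `view_classifier`.
#' @export
read_view_classifier <- function(path) {
  if (!file.exists(path)) stop_input("classifier file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$weights <- as.numeric(obj$weights)
  obj$standardizer$center <- as.numeric(obj$standardizer$center)
  obj$standardizer$scale <- as.numeric(obj$standardizer$scale)
  structure(obj, class = "view_classifier")
}
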