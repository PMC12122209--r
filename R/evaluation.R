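# Stratified k-fold cross-validation orchestration and the metric suite
# (balanced accuracy, sensitivity, specificity, precision, ROC AUC).

#' Assign samples to stratified cross-validation folds
#'
#' Shuffles within each class with a seeded RNG, then deals round-robin, so
#' per-fold class counts differ by at most 1 within each class — the
#' simplest scheme preserving the class distribution per fold.
#'
#' @param labels `"P"`/`"A"` vector.
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return An object of class `fold_assignment`: an integer vector of fold
#'   indices in `1..k`, with attributes `k` and `seed`.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2) stop_input("k must be >= 2")
  tab <- table(labels)
  small <- tab[tab < k]
  if (length(small) > 0) {
    stop_input("class '", names(small)[1], "' has only ", small[1],
               " members but k = ", k)
  }
  fold <- integer(length(labels))
  set.seed(as.integer(seed))
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(fold, k = k, seed = as.integer(seed), class = "fold_assignment")
}

#' ROC AUC by the rank statistic
#'
#' Mann-Whitney formulation: the probability that a random presence sample
#' outscores a random absence sample, with half credit for score ties
#' (mid-ranks). Equals brute-force all-pairs counting.
#'
#' @param score_P Numeric presence scores.
#' @param y_true `"P"`/`"A"` truth vector of the same length.
#' @return AUC in `[0, 1]`, or `NA` when either class is absent.
#' @export
auc_rank <- function(score_P, y_true) {
  y_true <- as.character(y_true)
  n_P <- sum(y_true == "P")
  n_A <- sum(y_true == "A")
  if (n_P == 0 || n_A == 0) return(NA_real_)
  r <- rank(score_P, ties.method = "average")
  (sum(r[y_true == "P"]) - n_P * (n_P + 1) / 2) / (n_P * n_A)
}

#' Compute the metric suite from truth, predictions and scores
#'
#' Confusion counts are exact, with P as the positive class. Ratios with a
#' zero denominator (e.g. precision when nothing was predicted P) are
#' flagged in `$undefined` and reported as `NA`, never silently coerced;
#' balanced accuracy is the exact mean of sensitivity and specificity.
#'
#' @param y_true,y_pred `"P"`/`"A"` vectors of equal length.
#' @param score_P Optional presence scores for AUC; when omitted AUC is
#'   flagged undefined.
#' @return An object of class `metric_set`: list with `tp`, `fp`, `tn`,
#'   `fn`, `sen`, `spe`, `pre`, `bac`, `auc`, and `undefined` (character
#'   vector of flagged metrics).
#' @export
compute_metrics <- function(y_true, y_pred, score_P = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop_input("y_true has length ", length(y_true), " but y_pred has ",
               length(y_pred))
  }
  if (!is.null(score_P) && length(score_P) != length(y_true)) {
    stop_input("score_P has length ", length(score_P), " but y_true has ",
               length(y_true))
  }
  tp <- sum(y_true == "P" & y_pred == "P")
  fn <- sum(y_true == "P" & y_pred == "A")
  tn <- sum(y_true == "A" & y_pred == "A")
  fp <- sum(y_true == "A" & y_pred == "P")
  metric_set(tp = tp, fp = fp, tn = tn, fn = fn,
             auc = if (is.null(score_P)) NA_real_ else auc_rank(score_P, y_true),
             auc_given = !is.null(score_P))
}

#' Build a metric set from confusion counts
#'
#' @param tp,fp,tn,fn Confusion counts with P as the positive class.
#' @param auc Optional precomputed AUC.
#' @param auc_given Whether scores were available (controls the flag).
#' @return A `metric_set` (see [compute_metrics()]).
#' @export
metric_set <- function(tp, fp, tn, fn, auc = NA_real_, auc_given = !is.na(auc)) {
  undefined <- character()
  sen <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sen"); NA_real_
  }
  spe <- if (tn + fp > 0) tn / (tn + fp) else {
    undefined <- c(undefined, "spe"); NA_real_
  }
  pre <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "pre"); NA_real_
  }
  bac <- if (!is.na(sen) && !is.na(spe)) (sen + spe) / 2 else {
    undefined <- c(undefined, "bac"); NA_real_
  }
  if (is.na(auc)) undefined <- c(undefined, "auc")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sen = sen, spe = spe, pre = pre, bac = bac, auc = auc,
                 undefined = undefined),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("BAC %.4f | SEN %.4f | SPE %.4f | PRE %.4f | AUC %.4f\n",
              x$bac, x$sen, x$spe, x$pre, x$auc))
  cat(sprintf("confusion: TP %d FP %d TN %d FN %d", x$tp, x$fp, x$tn, x$fn))
  if (length(x$undefined)) cat("  [undefined: ",
                               paste(x$undefined, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

.metric_names <- c("bac", "sen", "spe", "pre", "auc")

metrics_row <- function(fold, model, ms) {
  data.frame(fold = fold, model = model,
             bac = ms$bac, sen = ms$sen, spe = ms$spe, pre = ms$pre,
             auc = ms$auc, tp = ms$tp, fp = ms$fp, tn = ms$tn, fn = ms$fn,
             stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the two base classifiers and fusion
#'
#' For each fold: fits standardizer, linear SVM and Platt calibration for
#' each view on the training folds only; predicts the held-out fold; fuses
#' the two outputs; and computes the metric suite for the presence-view
#' classifier (`CP`), the absence-view classifier (`CA`), and the fusion.
#' Per-fold metrics are aggregated as mean and sample standard deviation
#' (n - 1). Undefined per-fold metrics are excluded from that metric's
#' aggregate with a warning.
#'
#' All randomness (fold shuffle, internal calibration splits) derives from
#' `seed`, so the report is reproducible end to end.
#'
#' @param manifest Labeled manifest `data.frame` (see [merge_labels()]), or
#'   a named `"P"`/`"A"` label vector.
#' @param view1 [feature_view()] of the presence-sensitive view (trains CP).
#' @param view2 [feature_view()] of the absence-sensitive view (trains CA).
#' @param k Number of folds (default 5).
#' @param seed Integer master seed.
#' @param cost SVM regularization constant.
#' @param score_mode `"platt"` or `"margin"` (see [train_view_classifier()]).
#' @param policy A [fusion_policy()].
#' @return An object of class `cv_report`: list with `per_fold`
#'   (data.frame), `aggregate` (data.frame of mean/sd per model x metric),
#'   `decisions` (per-sample fusion decisions with fold and truth), `folds`,
#'   and `config`.
#' @export
cross_validate <- function(manifest, view1, view2, k = 5, seed = 1, cost = 1,
                           score_mode = c("platt", "margin"),
                           policy = fusion_policy()) {
  score_mode <- match.arg(score_mode)
  labels <- if (is.data.frame(manifest)) {
    if (anyNA(manifest$label)) stop_input("manifest labels unset; call merge_labels()")
    stats::setNames(manifest$label, manifest$sample_id)
  } else {
    manifest
  }
  ids <- view1$sample_ids
  if (!identical(ids, view2$sample_ids)) {
    stop_input("view1 and view2 must share an identical sample id sequence")
  }
  y <- as_PA(labels, ids)

  folds <- stratified_folds(y, k = k, seed = derive_seed(seed, 1000))
  per_fold <- list()
  decisions <- list()
  models <- c("CP", "CA", "fusion")

  for (f in seq_len(k)) {
    te <- folds == f
    tr_view1 <- feature_view(view1$view_name, ids[!te], view1$matrix[!te, , drop = FALSE])
    tr_view2 <- feature_view(view2$view_name, ids[!te], view2$matrix[!te, , drop = FALSE])
    te_view1 <- feature_view(view1$view_name, ids[te], view1$matrix[te, , drop = FALSE])
    te_view2 <- feature_view(view2$view_name, ids[te], view2$matrix[te, , drop = FALSE])

    res <- tryCatch({
      clf1 <- train_view_classifier(tr_view1, y[!te], cost = cost,
                                    seed = derive_seed(seed, 100 * f + 1),
                                    score_mode = score_mode)
      clf2 <- train_view_classifier(tr_view2, y[!te], cost = cost,
                                    seed = derive_seed(seed, 100 * f + 2),
                                    score_mode = score_mode)
      out1 <- predict(clf1, te_view1)
      out2 <- predict(clf2, te_view2)
      fused <- fuse_outputs(out1, out2, policy)
      list(out1 = out1, out2 = out2, fused = fused)
    }, error = function(e) {
      stop_input("fold ", f, ": ", conditionMessage(e))
    })

    y_te <- y[te]
    per_fold[[f]] <- rbind(
      metrics_row(f, "CP", compute_metrics(y_te, res$out1$label, res$out1$score_P)),
      metrics_row(f, "CA", compute_metrics(y_te, res$out2$label, res$out2$score_P)),
      metrics_row(f, "fusion", compute_metrics(y_te, res$fused$fused_label,
                                               res$fused$fused_score_P))
    )
    dec <- res$fused
    dec$fold <- f
    dec$truth <- unname(y_te)
    decisions[[f]] <- dec
  }

  per_fold <- do.call(rbind, per_fold)
  agg <- aggregate_cv(per_fold, models)

  structure(list(
    per_fold = per_fold,
    aggregate = agg,
    decisions = do.call(rbind, decisions),
    folds = folds,
    config = list(k = k, seed = as.integer(seed), cost = cost,
                  score_mode = score_mode, policy = unclass(policy),
                  view1 = view1$view_name, view2 = view2$view_name)
  ), class = "cv_report")
}

aggregate_cv <- function(per_fold, models) {
  rows <- list()
  for (mdl in models) {
    sub <- per_fold[per_fold$model == mdl, , drop = FALSE]
    for (metric in .metric_names) {
      v <- sub[[metric]]
      if (anyNA(v)) {
        warning("model ", mdl, ": metric '", metric, "' undefined in ",
                sum(is.na(v)), " fold(s); excluded from its aggregate",
                call. = FALSE)
        v <- v[!is.na(v)]
      }
      rows[[length(rows) + 1]] <- data.frame(
        model = mdl, metric = metric,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n_folds = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("Stratified %d-fold cross-validation (seed %d)\n",
              x$config$k, x$config$seed))
  cat(format_cv_table(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Format an aggregate cross-validation table
#'
#' Human-readable model-by-metric table with `mean +/- sd` cells, in the
#' layout of comparative CV tables (models as rows; BAC, PRE, SEN, SPE, AUC
#' as columns).
#'
#' @param report A `cv_report`.
#' @param digits Digits after the decimal point.
#' @return Character vector of table lines.
#' @export
format_cv_table <- function(report, digits = 3) {
  agg <- report$aggregate
  models <- unique(agg$model)
  cols <- c("bac", "pre", "sen", "spe", "auc")
  header <- sprintf("%-8s %s", "Model",
                    paste(sprintf("%-15s", toupper(cols)), collapse = " "))
  lines <- vapply(models, function(mdl) {
    cells <- vapply(cols, function(metric) {
      r <- agg[agg$model == mdl & agg$metric == metric, ]
      if (nrow(r) == 0 || is.na(r$mean)) return(sprintf("%-15s", "--"))
      sprintf("%-15s", sprintf(paste0("%.", digits, "f \u00b1 %.", digits, "f"),
                               r$mean, ifelse(is.na(r$sd), 0, r$sd)))
    }, character(1))
    sprintf("%-8s %s", mdl, paste(cells, collapse = " "))
  }, character(1))
  c(header, lines)
}

#' Write cross-validation report files
#'
#' Writes `per_fold.csv`, `aggregate.csv`, `decisions.csv`, a plain-text
#' aggregate table (`report.txt`), and the resolved configuration
#' (`config.json`) into `dir`.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    per_fold = file.path(dir, "per_fold.csv"),
    aggregate = file.path(dir, "aggregate.csv"),
    decisions = file.path(dir, "decisions.csv"),
    table = file.path(dir, "report.txt"),
    config = file.path(dir, "config.json")
  )
  utils::write.csv(report$per_fold, paths["per_fold"], row.names = FALSE)
  utils::write.csv(report$aggregate, paths["aggregate"], row.names = FALSE)
  utils::write.csv(report$decisions, paths["decisions"], row.names = FALSE)
  writeLines(format_cv_table(report), paths["table"])
  jsonlite::write_json(report$config, paths["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
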