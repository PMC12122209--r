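test_that("stratified folds preserve class counts within 1 and are deterministic", {
  y <- rep(c("P", "A"), c(180, 57))
  f <- stratified_folds(y, k = 5, seed = 4)
  expect_equal(sort(unique(as.integer(f))), 1:5)
  per_fold_P <- table(f[y == "P"])
  per_fold_A <- table(f[y == "A"])
  expect_true(all(per_fold_P == 36))
  expect_true(all(per_fold_A %in% c(11, 12)))
  expect_equal(sum(per_fold_A), 57)

  expect_identical(stratified_folds(y, 5, seed = 4), f)
  expect_false(identical(as.integer(stratified_folds(y, 5, seed = 5)),
                         as.integer(f)))

  y2 <- rep(c("P", "A"), each = 10)
  f2 <- stratified_folds(y2, k = 5, seed = 1)
  expect_true(all(table(f2, y2) == 2))

  expect_error(stratified_folds(rep(c("P", "A"), c(20, 3)), k = 5),
               "class 'A' has only 3")
  expect_error(stratified_folds(y, k = 1), "k must be")
})

test_that("metric formulas match hand-computed values on fixed confusions", {
  # SEN = 170/180, SPE = 45/57, BAC = their mean, PRE = 170/182
  ms <- metric_set(tp = 170, fn = 10, tn = 45, fp = 12)
  expect_equal(round(ms$sen, 4), 0.9444)
  expect_equal(round(ms$spe, 4), 0.7895)
  expect_equal(round(ms$bac, 4), 0.8670)
  expect_equal(round(ms$pre, 4), 0.9341)

  y <- rep(c("P", "A"), c(3, 3))
  perfect <- compute_metrics(y, y, c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3))
  for (m in c("sen", "spe", "pre", "bac", "auc")) expect_equal(perfect[[m]], 1)

  all_p <- compute_metrics(y, rep("P", 6))
  expect_equal(all_p$sen, 1)
  expect_equal(all_p$spe, 0)
  expect_equal(all_p$bac, 0.5)
})

test_that("undefined ratios are flagged rather than propagated as NaN", {
  no_pred_p <- metric_set(tp = 0, fp = 0, tn = 5, fn = 3)
  expect_true("pre" %in% no_pred_p$undefined)
  expect_true(is.na(no_pred_p$pre))
  expect_false(is.nan(no_pred_p$bac))

  one_class <- compute_metrics(rep("P", 4), rep("P", 4), runif(4))
  expect_true(all(c("spe", "bac", "auc") %in% one_class$undefined))
  expect_error(compute_metrics(c("P", "A"), "P"), "length")
})

test_that("balanced accuracy identity holds to machine precision", {
  set.seed(77)
  for (i in 1:1000) {
    cm <- rpois(4, 20)
    if (cm[1] + cm[4] == 0 || cm[2] + cm[3] == 0) next
    ms <- metric_set(tp = cm[1], fp = cm[2], tn = cm[3], fn = cm[4])
    if (is.na(ms$bac)) next
    expect_identical(ms$bac, (ms$sen + ms$spe) / 2)
  }
})

test_that("rank AUC equals brute-force all-pairs counting and pROC", {
  brute_auc <- function(score, y) {
    p <- score[y == "P"]; a <- score[y == "A"]
    pairs <- outer(p, a, function(x, z) (x > z) + 0.5 * (x == z))
    mean(pairs)
  }
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    y <- c("P", "A", sample(c("P", "A"), n - 2, replace = TRUE))
    # duplicated values exercise the tie handling
    score <- sample(round(runif(n), 1), n)
    expect_equal(auc_rank(score, y), brute_auc(score, y))
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(13)
    y <- sample(c("P", "A"), 80, replace = TRUE, prob = c(0.7, 0.3))
    score <- runif(80) + 0.5 * (y == "P")
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                          levels = c("A", "P"), direction = "<",
                                          quiet = TRUE)))
    expect_equal(auc_rank(score, y), ref)
  }
  expect_true(is.na(auc_rank(runif(3), rep("P", 3))))
})

test_that("cross-validation report has the contracted shape", {
  ds <- generate_synthetic(asymmetry_preset(3, 2, n_P = 180, n_A = 57, seed = 1))
  cvrep <- cross_validate(ds$manifest, ds$view1, ds$view2, k = 5, seed = 1)
  expect_equal(nrow(cvrep$per_fold), 5 * 3)
  expect_setequal(unique(cvrep$per_fold$model), c("CP", "CA", "fusion"))
  expect_equal(nrow(cvrep$aggregate), 3 * 5)
  expect_equal(nrow(cvrep$decisions), 237)
  # every sample tests exactly once: fold union is the dataset
  expect_setequal(cvrep$decisions$sample_id, ds$view1$sample_ids)
  # aggregate is recomputable from per_fold at full precision
  for (i in seq_len(nrow(cvrep$aggregate))) {
    r <- cvrep$aggregate[i, ]
    v <- cvrep$per_fold[[r$metric]][cvrep$per_fold$model == r$model]
    expect_equal(r$mean, mean(v))
    expect_equal(r$sd, sd(v))
  }
})

test_that("identical config and seed reproduce the report exactly", {
  ds <- generate_synthetic(asymmetry_preset(3, 2, n_A = 30, seed = 2))
  r1 <- cross_validate(ds$manifest, ds$view1, ds$view2, k = 4, seed = 9)
  r2 <- cross_validate(ds$manifest, ds$view1, ds$view2, k = 4, seed = 9)
  expect_identical(r1, r2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cv_report(r1, d1)
  write_cv_report(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("held-out predictions come from models fitted without the test rows", {
  ds <- generate_synthetic(asymmetry_preset(3, 2, n_A = 30, seed = 3))
  seed <- 5
  cvrep <- cross_validate(ds$manifest, ds$view1, ds$view2, k = 5, seed = seed)
  folds <- cvrep$folds
  ids <- ds$view1$sample_ids
  y <- ds$truth

  for (f in c(1, 4)) {
    te <- folds == f
    # refit from scratch on ONLY the training rows, mirroring the derived seeds
    refit <- function(v, off) {
      train_view_classifier(
        feature_view(v$view_name, ids[!te], v$matrix[!te, , drop = FALSE]),
        y[!te], seed = viewfuse:::derive_seed(seed, 100 * f + off))
    }
    out1 <- predict(refit(ds$view1, 1),
                    feature_view("view1", ids[te], ds$view1$matrix[te, , drop = FALSE]))
    out2 <- predict(refit(ds$view2, 2),
                    feature_view("view2", ids[te], ds$view2$matrix[te, , drop = FALSE]))
    fused <- fuse_outputs(out1, out2)
    got <- cvrep$decisions[cvrep$decisions$fold == f, ]
    expect_equal(got$fused_label, fused$fused_label)
    expect_equal(got$fused_score_P, fused$fused_score_P)
  }
})

test_that("margin score mode runs end to end and differs only in scores", {
  ds <- generate_synthetic(asymmetry_preset(3, 2, n_A = 30, seed = 4))
  r_platt <- cross_validate(ds$manifest, ds$view1, ds$view2, k = 3, seed = 1)
  r_margin <- cross_validate(ds$manifest, ds$view1, ds$view2, k = 3, seed = 1,
                             score_mode = "margin")
  expect_identical(as.integer(r_platt$folds), as.integer(r_margin$folds))
  expect_false(identical(r_platt$decisions$fused_score_P,
                         r_margin$decisions$fused_score_P))
})

test_that("aggregate formatting mirrors a comparative mean-sd table", {
  ds <- generate_synthetic(asymmetry_preset(3, 2, n_A = 30, seed = 6))
  cvrep <- cross_validate(ds$manifest, ds$view1, ds$view2, k = 3, seed = 1)
  lines <- format_cv_table(cvrep)
  expect_length(lines, 4)  # header + CP + CA + fusion
  expect_match(lines[1], "BAC")
  expect_match(lines[4], "^fusion")
  expect_match(lines[2], "\\d\\.\\d{3} ± \\d\\.\\d{3}")
})
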