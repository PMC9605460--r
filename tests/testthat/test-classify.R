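# Severity graders, cross-validation reporting, early stopping.

test_that("all three model kinds separate well-separated clusters", {
  feats <- gaussian_blob_features(100, seed = 1)
  for (kind in c("tree", "random_forest", "rotation_forest")) {
    cfg <- classifier_config(kind, n_trees = 25, seed = 5)
    model <- fit_severity(feats, cfg)
    pred <- predict_severity(model, feats)
    expect_equal(as.integer(as.character(pred$grade)),
                 as.integer(as.character(feats$grade)),
                 label = kind)
  }
})

test_that("training is deterministic for a fixed seed", {
  feats <- gaussian_blob_features(50, seed = 2)
  for (kind in c("random_forest", "rotation_forest")) {
    cfg <- classifier_config(kind, n_trees = 15, seed = 42)
    p1 <- predict_severity(fit_severity(feats, cfg), feats)
    p2 <- predict_severity(fit_severity(feats, cfg), feats)
    expect_identical(p1, p2, label = kind)
  }
})

test_that("degenerate training inputs error clearly", {
  feats <- gaussian_blob_features(20, seed = 3)
  one_class <- dplyr::filter(feats, grade == 1)
  expect_error(fit_severity(one_class), "2 severity classes")
  feats$f1 <- NA_real_
  expect_error(fit_severity(feats), "entirely missing")
})

test_that("rows with flagged feature values are dropped with a warning", {
  feats <- gaussian_blob_features(30, seed = 4)
  feats$f2[c(1, 5)] <- NA_real_
  expect_warning(fit_severity(feats, classifier_config("tree")), "2 row")
})

test_that("prediction errors on schema mismatch, names missing columns", {
  feats <- gaussian_blob_features(30, seed = 5)
  model <- fit_severity(feats, classifier_config("tree"))
  expect_error(predict_severity(model, feats[, c("f1", "grade")]),
               "f2")
})

test_that("probability ties break toward the lower grade", {
  # constant feature: the tree cannot split, every class is equally likely
  feats <- tibble::tibble(f1 = rep(1, 40),
                          grade = factor(rep(1:4, 10), levels = 1:4,
                                         ordered = TRUE))
  model <- fit_severity(feats, classifier_config("tree"))
  pred <- predict_severity(model, tibble::tibble(f1 = 1))
  expect_equal(pred$p1, 0.25, tolerance = 1e-9)
  expect_equal(as.integer(as.character(pred$grade)), 1L)
})

test_that("cross-validation reports a consistent pooled confusion matrix", {
  feats <- gaussian_blob_features(30, seed = 6)
  cv <- cross_validate_severity(feats, classifier_config("random_forest",
                                                         n_trees = 25,
                                                         n_folds = 5,
                                                         seed = 9))
  expect_equal(sum(cv$confusion_matrix), nrow(feats))
  expect_equal(sum(diag(cv$confusion_matrix)) / sum(cv$confusion_matrix),
               cv$accuracy)
  expect_equal(as.integer(rowSums(cv$confusion_matrix)),
               as.integer(table(feats$grade)))
  expect_gte(cv$accuracy, 0.99)
  expect_gte(cv$kappa, 0.98)
  expect_true(cv$rmse >= 0 && cv$mae >= 0)
  # probabilities pooled out-of-fold rows each sum to 1
  psum <- rowSums(as.matrix(cv$predictions[, c("p1", "p2", "p3", "p4")]))
  expect_true(all(abs(psum - 1) < 1e-9))
})

test_that("kappa is 1 for perfect agreement and ~0 for chance", {
  truth <- rep(1:4, each = 25)
  prob <- outer(truth, 1:4, `==`) * 1
  rep_perfect <- vesseltort:::evaluation_report(truth, truth, prob,
                                                classifier_config())
  expect_equal(rep_perfect$kappa, 1)
  expect_equal(rep_perfect$accuracy, 1)
  expect_equal(rep_perfect$rmse, 0)
  set.seed(8)
  guess <- sample(1:4, 100, replace = TRUE)
  rep_null <- vesseltort:::evaluation_report(truth, guess,
                                             matrix(0.25, 100, 4),
                                             classifier_config())
  expect_lt(abs(rep_null$kappa), 0.15)
})

test_that("fold construction rejects classes smaller than n_folds", {
  feats <- gaussian_blob_features(5, seed = 7)
  expect_error(cross_validate_severity(feats,
                                       classifier_config(n_folds = 10)),
               "smaller n_folds")
})

test_that("permuting informative features degrades CV accuracy", {
  ds <- generate_labeled_dataset(n_per_grade = 8, seed = 33)
  lab <- join_labels(ds$images, ds$labels)
  cfg <- classifier_config("tree", seed = 3, n_folds = 4)
  base <- cross_validate_severity(lab, cfg)
  set.seed(4)
  broken <- lab
  metric_cols <- grep("^(arc|chord|dm|df|td|soam|icm|tau|sd_avc|n_avc)",
                      names(broken), value = TRUE)
  for (col in metric_cols) {
    broken[[col]] <- sample(broken[[col]])
  }
  degraded <- cross_validate_severity(broken, cfg)
  expect_gt(base$accuracy, degraded$accuracy)
})

test_that("early stopping honors rounds, tolerance and budget", {
  expect_equal(early_stopping_index(rep(0.5, 50)), 3L)      # flat series
  improving <- 1 / (1:100)                                  # big improvements
  expect_equal(early_stopping_index(improving,
                                    stopping_tolerance = 1e-6), 100L)
  # plateau at index 40: stop within stopping_rounds evaluations after it
  series <- c(seq(1, 0.1, length.out = 40), rep(0.1, 60))
  stop_at <- early_stopping_index(series, stopping_rounds = 3,
                                  stopping_tolerance = 0.0005,
                                  max_trees = 500)
  expect_gte(stop_at, 40L)
  expect_lte(stop_at, 43L)
  expect_error(early_stopping_index(numeric(0)), "empty")
})

test_that("tidy/glance/autoplot expose the evaluation report", {
  feats <- gaussian_blob_features(20, seed = 10)
  cv <- cross_validate_severity(feats, classifier_config("tree", n_folds = 4,
                                                         seed = 2))
  td <- tidy(cv)
  expect_equal(td$grade, 1:4)
  expect_true(all(c("tpr", "fpr", "precision", "fscore", "roc_auc")
                  %in% names(td)))
  gl <- glance(cv)
  expect_equal(gl$accuracy, cv$accuracy)
  expect_s3_class(autoplot(cv), "ggplot")
  model <- fit_severity(feats, classifier_config("tree"))
  expect_equal(glance(model)$n_features, 3L)
})

test_that("models survive a save/load round trip", {
  feats <- gaussian_blob_features(25, seed = 11)
  model <- fit_severity(feats, classifier_config("random_forest",
                                                 n_trees = 10, seed = 1))
  f <- withr::local_tempfile(fileext = ".rds")
  save_severity_model(model, f)
  back <- load_severity_model(f)
  expect_identical(predict_severity(back, feats),
                   predict_severity(model, feats))
  expect_error(load_severity_model("does/not/exist.rds"), "not found")
})
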