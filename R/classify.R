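# Severity grading: entropy decision tree, rotation forest, random forest
# with randomized split thresholds; stratified k-fold evaluation.

#' Classifier configuration
#'
#' Bundles the grading hyperparameters. Defaults follow the tuned operating
#' point of the method: 105 trees with early stopping monitored on RMSE over
#' 3 consecutive evaluations at tolerance 0.0005, out of a 500-tree budget.
#'
#' @param model_kind `"tree"` (entropy/information-gain decision tree,
#'   C4.5-style), `"rotation_forest"` (PCA-rotated subspace ensemble) or
#'   `"random_forest"` (bootstrap ensemble with randomized split thresholds).
#' @param n_trees Ensemble size.
#' @param max_trees Upper budget for early stopping.
#' @param stopping_rounds,stopping_metric,stopping_tolerance Early-stopping
#'   monitor parameters (see [early_stopping_index()]).
#' @param n_folds Cross-validation folds.
#' @param seed Integer seed; a fixed seed makes every run fully reproducible.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(model_kind = c("random_forest", "tree",
                                             "rotation_forest"),
                              n_trees = 105, max_trees = 500,
                              stopping_rounds = 3, stopping_metric = "RMSE",
                              stopping_tolerance = 0.0005,
                              n_folds = 10, seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(n_trees >= 1, n_folds >= 2)
  structure(list(model_kind = model_kind, n_trees = n_trees,
                 max_trees = max_trees, stopping_rounds = stopping_rounds,
                 stopping_metric = stopping_metric,
                 stopping_tolerance = stopping_tolerance,
                 n_folds = n_folds, seed = as.integer(seed)),
            class = "classifier_config")
}

# Feature matrix / response extraction with missing-value policy (rows with
# flagged values are dropped, the default documented behavior).
prepare_training <- function(features) {
  stopifnot("grade" %in% names(features))
  y <- factor(as.integer(as.character(features$grade)), levels = 1:4)
  x <- dplyr::select(features, -dplyr::any_of(c("grade", "image_id")))
  x <- dplyr::select(x, dplyr::where(is.numeric))
  if (ncol(x) == 0) abort("no numeric feature columns")
  empty <- vapply(x, function(v) all(is.na(v)), logical(1))
  if (any(empty)) {
    abort(paste0("feature column(s) entirely missing: ",
                 paste(names(x)[empty], collapse = ", ")))
  }
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    warn(sprintf("dropping %d row(s) with flagged feature values",
                 sum(!keep)))
  }
  x <- x[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  if (nlevels(y) < 2) abort("training needs at least 2 severity classes")
  list(x = as.data.frame(x), y = y, feature_cols = names(x))
}

#' Fit a severity grading model
#'
#' Trains one of the three graders on a labeled image (or segment) feature
#' table:
#' * `tree` — a single decision tree split on information gain with
#'   cost-complexity pruning (a C4.5-style learner);
#' * `rotation_forest` — an ensemble whose trees each see the data after a
#'   principal-component rotation of random feature subsets fitted on a
#'   bootstrap sample;
#' * `random_forest` — bagged trees where candidate split thresholds are
#'   drawn at random and the best random threshold is kept (extremely
#'   randomized splitting), majority/probability voting across trees.
#'
#' @param features Labeled tibble from [join_labels()] (numeric feature
#'   columns + `grade`).
#' @param config A [classifier_config()]; its `model_kind`, `n_trees` and
#'   `seed` are honored.
#' @return A `severity_model` object.
#' @export
fit_severity <- function(features, config = classifier_config()) {
  prep <- prepare_training(features)
  set.seed(config$seed)
  fit <- switch(config$model_kind,
    tree = {
      d <- cbind(grade = prep$y, prep$x)
      rpart::rpart(grade ~ ., data = d, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(cp = 0.01, minsplit = 10,
                                                  xval = 0))
    },
    random_forest = ranger::ranger(
      x = prep$x, y = prep$y, num.trees = config$n_trees,
      probability = TRUE, splitrule = "extratrees", num.random.splits = 1,
      replace = TRUE, seed = config$seed, num.threads = 1
    ),
    rotation_forest = fit_rotation_forest(prep$x, prep$y,
                                          n_trees = config$n_trees,
                                          seed = config$seed)
  )
  structure(list(kind = config$model_kind, fit = fit,
                 feature_cols = prep$feature_cols,
                 levels = levels(prep$y), config = config,
                 version = "1"),
            class = "severity_model")
}

# Rotation forest: each tree is an information-gain tree trained on the data
# after a block-diagonal PCA rotation. Feature columns are randomly
# partitioned into subsets of ~3; each subset's rotation is the PCA loading
# matrix fitted on a 75% bootstrap sample.
fit_rotation_forest <- function(x, y, n_trees = 105, subset_size = 3,
                                sample_frac = 0.75, seed = 1L) {
  set.seed(seed)
  p <- ncol(x)
  xm <- as.matrix(x)
  centers <- colMeans(xm)
  xc <- sweep(xm, 2, centers)
  trees <- purrr::map(seq_len(n_trees), function(t) {
    perm <- sample(p)
    groups <- split(perm, ceiling(seq_along(perm) / subset_size))
    rot <- matrix(0, p, p)
    for (g in groups) {
      rows <- sample(nrow(xc), size = max(2, round(sample_frac * nrow(xc))),
                     replace = TRUE)
      sub <- xc[rows, g, drop = FALSE]
      pc <- tryCatch(stats::prcomp(sub, center = FALSE, scale. = FALSE)$rotation,
                     error = function(e) diag(length(g)))
      if (ncol(pc) < length(g)) { # rank deficiency: pad with identity columns
        pad <- diag(length(g))[, seq(ncol(pc) + 1, length(g)), drop = FALSE]
        pc <- cbind(pc, pad)
      }
      rot[g, g] <- pc
    }
    xr <- as.data.frame(xc %*% rot)
    names(xr) <- paste0("r", seq_len(p))
    fit <- rpart::rpart(y ~ ., data = cbind(y = y, xr), method = "class",
                        parms = list(split = "information"),
                        control = rpart::rpart.control(cp = 0.0, minsplit = 5,
                                                       xval = 0))
    list(rotation = rot, tree = fit)
  })
  list(trees = trees, centers = centers, levels = levels(y))
}

predict_rotation_forest <- function(model, x) {
  xc <- sweep(as.matrix(x), 2, model$centers)
  probs <- purrr::map(model$trees, function(tr) {
    xr <- as.data.frame(xc %*% tr$rotation)
    names(xr) <- paste0("r", seq_len(ncol(xr)))
    stats::predict(tr$tree, xr, type = "prob")
  })
  Reduce(`+`, probs) / length(probs)
}

#' Predict severity grades with class probabilities
#'
#' Averages the ensemble's class probabilities (a single tree's leaf class
#' frequencies) and assigns the grade with the highest probability;
#' probability ties break deterministically toward the lower (less severe)
#' grade.
#'
#' @param model A `severity_model` from [fit_severity()].
#' @param features Feature tibble with the training feature columns.
#' @return Tibble: `grade` (ordered factor) and probability columns
#'   `p1`..`p4` (zero-filled for classes absent at training).
#' @export
predict_severity <- function(model, features) {
  missing <- setdiff(model$feature_cols, names(features))
  if (length(missing)) {
    abort(paste0("feature schema mismatch; missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.data.frame(features)[, model$feature_cols, drop = FALSE]
  probs <- switch(model$kind,
    tree = stats::predict(model$fit, x, type = "prob"),
    random_forest = stats::predict(model$fit, data = x,
                                   num.threads = 1)$predictions,
    rotation_forest = predict_rotation_forest(model$fit, x)
  )
  probs <- as.matrix(probs)
  full <- matrix(0, nrow(probs), 4, dimnames = list(NULL, as.character(1:4)))
  full[, colnames(probs)] <- probs
  rownames(full) <- NULL
  grade_idx <- max.col(full, ties.method = "first") # first = lower grade
  tibble(
    grade = factor(grade_idx, levels = 1:4, ordered = TRUE),
    p1 = unname(full[, 1]), p2 = unname(full[, 2]),
    p3 = unname(full[, 3]), p4 = unname(full[, 4])
  )
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin over folds.
stratified_folds <- function(y, k, seed) {
  counts <- table(y)
  short <- names(counts)[counts > 0 & counts < k]
  if (length(short)) {
    abort(paste0("class(es) with fewer than n_folds members: ",
                 paste(short, collapse = ", "),
                 "; use a smaller n_folds"))
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold[i] <- rep_len(seq_len(k), length(i))[sample.int(length(i))]
  }
  fold
}

#' Cross-validate a severity grader
#'
#' Stratified k-fold cross-validation: the model is refit on each training
#' split and out-of-fold class probabilities are pooled into a single
#' evaluation — accuracy, Cohen's kappa on the pooled 4x4 confusion matrix
#' (rows = actual, columns = predicted), RMSE and MAE between the predicted
#' probability vectors and the one-hot true classes (averaged over samples
#' and classes, the usual multiclass convention), and per-class TPR, FPR,
#' precision, F-score and one-vs-rest ROC-AUC.
#'
#' @inheritParams fit_severity
#' @return A `severity_cv` object; see [tidy.severity_cv()],
#'   [glance.severity_cv()], [autoplot.severity_cv()].
#' @export
cross_validate_severity <- function(features, config = classifier_config()) {
  prep <- prepare_training(features)
  y <- prep$y
  folds <- stratified_folds(y, config$n_folds, config$seed)
  prob <- matrix(NA_real_, length(y), 4,
                 dimnames = list(NULL, as.character(1:4)))
  pred <- integer(length(y))
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f
    model <- fit_severity(
      cbind(grade = y[tr], prep$x[tr, , drop = FALSE]),
      fold_cfg
    )
    p <- predict_severity(model, prep$x[!tr, , drop = FALSE])
    prob[!tr, ] <- as.matrix(p[, c("p1", "p2", "p3", "p4")])
    pred[!tr] <- as.integer(as.character(p$grade))
  }
  truth <- as.integer(as.character(y))
  evaluation_report(truth, pred, prob, config)
}

# Pooled evaluation report from true grades, predicted grades and the
# predicted probability matrix.
evaluation_report <- function(truth, pred, prob, config) {
  cm <- table(actual = factor(truth, levels = 1:4),
              predicted = factor(pred, levels = 1:4))
  n <- sum(cm)
  accuracy <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (accuracy - pe) / (1 - pe) else 1
  onehot <- outer(truth, 1:4, `==`) * 1
  rmse <- sqrt(mean((prob - onehot)^2))
  mae <- mean(abs(prob - onehot))
  per_class <- purrr::map_dfr(1:4, function(g) {
    tp <- cm[g, g]; fn <- sum(cm[g, ]) - tp
    fp <- sum(cm[, g]) - tp; tn <- n - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    fscore <- if (!is.na(prec) && !is.na(tpr) && prec + tpr > 0) {
      2 * prec * tpr / (prec + tpr)
    } else NA_real_
    auc <- if (sum(truth == g) > 0 && sum(truth != g) > 0) {
      as.numeric(pROC::auc(pROC::roc(truth == g, prob[, g], quiet = TRUE,
                                     direction = "<")))
    } else NA_real_
    tibble(grade = g,
           tpr = tpr,
           fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
           precision = prec, fscore = fscore, roc_auc = auc)
  })
  structure(list(accuracy = accuracy, kappa = kappa,
                 confusion_matrix = unclass(cm), rmse = rmse, mae = mae,
                 per_class = per_class, n = n,
                 predictions = tibble(truth = truth, predicted = pred,
                                      p1 = prob[, 1], p2 = prob[, 2],
                                      p3 = prob[, 3], p4 = prob[, 4]),
                 config = config),
            class = "severity_cv")
}

#' @export
print.severity_cv <- function(x, ...) {
  cat(sprintf("Severity grading cross-validation (%s, %d folds, seed %d)\n",
              x$config$model_kind, x$config$n_folds, x$config$seed))
  cat(sprintf("  accuracy %.4f | kappa %.4f | RMSE %.4f | MAE %.4f | n = %d\n",
              x$accuracy, x$kappa, x$rmse, x$mae, x$n))
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(x$confusion_matrix)
  invisible(x)
}

#' Early-stopping monitor for ensemble growth
#'
#' Emulates the convergence rule used when growing the forest: after each
#' scored evaluation, the improvement of the validation metric (RMSE) over
#' the best earlier value is tracked; growth stops at the first evaluation
#' where the last `stopping_rounds` evaluations all improved by less than
#' `stopping_tolerance`. A strictly flat series therefore stops after
#' `stopping_rounds` evaluations, while a series that keeps improving by
#' more than the tolerance runs to the end of the budget.
#'
#' @param rmse_series Per-evaluation validation RMSE values (one per tree
#'   added, or per scoring event).
#' @param stopping_rounds Number of consecutive low-improvement evaluations
#'   required to stop.
#' @param stopping_tolerance Minimum improvement that counts as progress.
#' @param max_trees Budget cap on the returned index.
#' @return Integer: the number of evaluations (trees) kept.
#' @export
early_stopping_index <- function(rmse_series, stopping_rounds = 3,
                                 stopping_tolerance = 0.0005,
                                 max_trees = 500) {
  n <- length(rmse_series)
  if (n == 0) abort("empty RMSE series")
  imp <- numeric(n)
  imp[1] <- 0
  if (n > 1) {
    best <- cummin(rmse_series)
    imp[2:n] <- best[1:(n - 1)] - rmse_series[2:n]
  }
  for (k in seq(stopping_rounds, n)) {
    window <- imp[(k - stopping_rounds + 1):k]
    if (all(window < stopping_tolerance)) return(min(k, max_trees))
  }
  min(n, max_trees)
}

#' Save / load a severity model
#'
#' Persists the fitted model together with its feature schema, configuration
#' and a format version field.
#'
#' @param model A `severity_model`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_severity_model <- function(model, path) {
  stopifnot(inherits(model, "severity_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_severity_model
#' @export
load_severity_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  model <- readRDS(path)
  if (!inherits(model, "severity_model")) abort("not a severity model file")
  model
}
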