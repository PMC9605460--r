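# broom-style accessors for evaluation and model objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation report
#'
#' @param x A `severity_cv` from [cross_validate_severity()].
#' @param ... Unused.
#' @return Per-class tibble: `grade`, `tpr`, `fpr`, `precision`, `fscore`,
#'   `roc_auc`.
#' @export
tidy.severity_cv <- function(x, ...) {
  x$per_class
}

#' One-row summary of a cross-validation report
#'
#' @inheritParams tidy.severity_cv
#' @return Tibble: `model_kind`, `n_folds`, `n`, `accuracy`, `kappa`,
#'   `rmse`, `mae`, `macro_roc_auc`.
#' @export
glance.severity_cv <- function(x, ...) {
  tibble(
    model_kind = x$config$model_kind, n_folds = x$config$n_folds, n = x$n,
    accuracy = x$accuracy, kappa = x$kappa, rmse = x$rmse, mae = x$mae,
    macro_roc_auc = mean(x$per_class$roc_auc, na.rm = TRUE)
  )
}

#' One-row summary of a fitted severity model
#'
#' @param x A `severity_model`.
#' @param ... Unused.
#' @return Tibble: `model_kind`, `n_features`, `n_trees`, `seed`.
#' @export
glance.severity_model <- function(x, ...) {
  tibble(model_kind = x$kind, n_features = length(x$feature_cols),
         n_trees = if (x$kind == "tree") 1L else x$config$n_trees,
         seed = x$config$seed)
}
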