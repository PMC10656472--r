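# broom-style accessors for the fitted result objects

#' Tidy a nested CV result
#'
#' @param x A `tbq_nested_cv`.
#' @param ... Unused.
#' @return One row per outer fold: `rep`, `fold`, `auc` and the chosen
#'   hyperparameters.
#' @export
tidy.tbq_nested_cv <- function(x, ...) x$folds

#' @rdname tidy.tbq_nested_cv
#' @return `glance()`: one row with `mean_auc`, `sd_auc`, `n_folds`,
#'   `n_skipped`, and the BCa-free summary of the run.
#' @export
glance.tbq_nested_cv <- function(x, ...) {
  tibble::tibble(
    mean_auc = mean(x$auc),
    sd_auc = stats::sd(x$auc),
    n_folds = length(x$auc),
    n_skipped = x$skipped,
    top_feature = names(sort(x$importance, decreasing = TRUE))[1L]
  )
}

#' Tidy a BCa interval
#' @param x A `tbq_bca`.
#' @param ... Unused.
#' @export
tidy.tbq_bca <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, lower = x$lower, upper = x$upper,
                 level = x$level, B = x$B)
}

#' Tidy an experiment grid
#'
#' @param x A `tbq_experiment_grid`.
#' @param ... Unused.
#' @return The grid without its list-column: `variant`, `experiment`,
#'   `mean_auc`, `sd_auc`, `n_folds`.
#' @export
tidy.tbq_experiment_grid <- function(x, ...) {
  out <- as.data.frame(x)[, c("variant", "experiment", "mean_auc", "sd_auc", "n_folds")]
  tibble::as_tibble(out)
}
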