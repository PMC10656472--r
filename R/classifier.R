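#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive outscores
#' a randomly chosen negative, ties counted one half (equivalent to the
#' Mann-Whitney U statistic normalised by the number of positive-negative
#' pairs).
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param labels Logical/0-1/factor labels; for factors the level
#'   `"TILsum_High"` (or the second level) is positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @noRd
as_positive <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.character(labels)
    if (any(labels == "TILsum_High")) labels == "TILsum_High"
    else labels == sort(unique(labels))[2L]
  } else {
    labels != 0
  }
}

#' Nested cross-validation configuration
#'
#' Outer repeated stratified k-fold for unbiased performance estimation,
#' inner stratified k-fold for hyperparameter selection. The default of 6
#' outer folds repeated 10 times yields 60 outer AUC values per experiment.
#'
#' @param outer_folds,outer_repeats,inner_folds Fold structure.
#' @param search_budget Random hyperparameter draws per outer split.
#' @param stratified Stratify folds by outcome (always recommended).
#' @param seed Master seed; identical seeds give identical AUC vectors,
#'   importances and models.
#' @return A `tbq_cv_config`.
#' @export
cv_config <- function(outer_folds = 6L, outer_repeats = 10L, inner_folds = 5L,
                      search_budget = 8L, stratified = TRUE, seed = 1L) {
  structure(
    list(outer_folds = as.integer(outer_folds),
         outer_repeats = as.integer(outer_repeats),
         inner_folds = as.integer(inner_folds),
         search_budget = as.integer(search_budget),
         stratified = isTRUE(stratified),
         seed = as.integer(seed)),
    class = "tbq_cv_config"
  )
}

# stratified fold assignment: within each class, shuffled patients are dealt
# round-robin over folds
#' @noRd
stratified_folds <- function(y, k, stratified = TRUE) {
  fold <- integer(length(y))
  strata <- if (stratified) split(seq_along(y), y) else list(seq_along(y))
  for (idx in strata) {
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# ---- the classification pipeline -------------------------------------------
# imputation (median) -> standardisation -> minority oversampling ->
# univariate feature selection (|AUC - 0.5| ranking) -> probability forest.
# Oversampling happens inside training folds only, after splitting, so no
# synthetic duplicate ever leaks into a test side.

#' @noRd
sample_hyperparams <- function(budget, p) {
  k_opts <- unique(pmin(c(2L, 4L, 8L, 16L, 32L, p), p))
  tibble::tibble(
    num_trees = sample(c(100L, 200L, 300L, 500L), budget, replace = TRUE),
    mtry_frac = stats::runif(budget, 0.1, 0.9),
    min_node = sample(c(1L, 3L, 5L, 10L), budget, replace = TRUE),
    k = sample(k_opts, budget, replace = TRUE),
    seed = sample.int(2L^30L, budget)
  )
}

#' @noRd
fit_pipeline <- function(x, y, params) {
  med <- apply(x, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  x <- scale(x, center = ctr, scale = scl)

  pos <- as_positive(y)
  idx <- seq_along(y)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos > 0L && n_neg > 0L && n_pos != n_neg) {
    minority <- if (n_pos < n_neg) which(pos) else which(!pos)
    extra <- minority[sample.int(length(minority), abs(n_pos - n_neg),
                                 replace = TRUE)]
    idx <- c(idx, extra)
  }
  xb <- x[idx, , drop = FALSE]
  yb <- factor(ifelse(pos[idx], "TILsum_High", "TILsum_Low"),
               levels = c("TILsum_Low", "TILsum_High"))

  # univariate filter: per-feature separation measured by |AUC - 0.5|
  sep <- vapply(seq_len(ncol(xb)), function(j) abs(auc(xb[, j], yb) - 0.5),
                numeric(1))
  keep <- order(sep, decreasing = TRUE)[seq_len(min(params$k, ncol(xb)))]
  keep <- sort(keep)

  fit <- ranger::ranger(
    x = as.data.frame(xb[, keep, drop = FALSE]), y = yb,
    num.trees = params$num_trees,
    mtry = max(1L, floor(params$mtry_frac * length(keep))),
    min.node.size = params$min_node,
    probability = TRUE, importance = "impurity",
    seed = params$seed, num.threads = 1L
  )
  structure(
    list(fit = fit, medians = med, center = ctr, scale = scl, keep = keep,
         feature_names = colnames(x), params = params),
    class = "tbq_pipeline"
  )
}

#' @noRd
predict_pipeline <- function(pipe, x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- pipe$medians[j]
  x <- scale(x, center = pipe$center, scale = pipe$scale)
  pr <- stats::predict(pipe$fit, data = as.data.frame(x[, pipe$keep, drop = FALSE]),
                       num.threads = 1L)$predictions
  pr[, "TILsum_High"]
}

#' Nested cross-validation of the TILsum_High classifier
#'
#' For each outer split: a seeded randomized search over the pipeline
#' hyperparameters (tree count, mtry, node size, number of selected features)
#' is scored by inner-fold AUC on the outer-training patients only, the best
#' pipeline is refit on the full outer-training side, and AUC is measured
#' once on the held-out outer-test patients. Patient identity never crosses
#' a split (asserted every fold); outer-test folds containing a single class
#' are skipped and reported. Feature importances are Mean Decrease Impurity
#' from each outer fold's final forest, averaged over folds on the full
#' feature space and normalised to sum to 1.
#'
#' @param data Tibble from [build_feature_table()]: `id`, `label`, features.
#' @param outcome,id Column names of the label and patient identifier.
#' @param config A [cv_config()].
#' @return A `tbq_nested_cv`: outer AUC vector, per-fold tibble with chosen
#'   hyperparameters, normalised importances, the refit final model, skipped
#'   folds, and the config. `tidy()`, `glance()` and `autoplot()` methods
#'   apply.
#' @export
nested_cv <- function(data, outcome = "label", id = "id", config = cv_config()) {
  y <- data[[outcome]]
  ids <- as.character(data[[id]])
  feat_cols <- setdiff(names(data), c(outcome, id))
  x <- as.matrix(data[, feat_cols])
  storage.mode(x) <- "double"
  if (length(unique(as_positive(y))) < 2L) stop("both outcome classes required")

  folds_tbl <- list()
  aucs <- numeric(0)
  imp_sum <- stats::setNames(numeric(length(feat_cols)), feat_cols)
  imp_n <- 0L
  skipped <- 0L

  with_seed(config$seed, {
    for (rep in seq_len(config$outer_repeats)) {
      fold <- stratified_folds(y, config$outer_folds, config$stratified)
      for (f in seq_len(config$outer_folds)) {
        te <- which(fold == f)
        tr <- which(fold != f)
        if (length(intersect(ids[tr], ids[te]))) {
          stop("patient leakage detected between outer train and test")
        }
        if (length(unique(as_positive(y[te]))) < 2L ||
            length(unique(as_positive(y[tr]))) < 2L) {
          skipped <- skipped + 1L
          next
        }
        cand <- sample_hyperparams(config$search_budget, ncol(x))
        inner_fold <- stratified_folds(y[tr], config$inner_folds, config$stratified)
        inner_seed_state <- .Random.seed
        cand_auc <- vapply(seq_len(nrow(cand)), function(ci) {
          prm <- as.list(cand[ci, ])
          a <- vapply(seq_len(config$inner_folds), function(g) {
            ite <- tr[inner_fold == g]
            itr <- tr[inner_fold != g]
            if (length(unique(as_positive(y[ite]))) < 2L ||
                length(unique(as_positive(y[itr]))) < 2L) return(NA_real_)
            pipe <- fit_pipeline(x[itr, , drop = FALSE], y[itr], prm)
            auc(predict_pipeline(pipe, x[ite, , drop = FALSE]), y[ite])
          }, numeric(1))
          mean(a, na.rm = TRUE)
        }, numeric(1))
        assign(".Random.seed", inner_seed_state, envir = globalenv())
        best <- which.max(cand_auc)
        prm <- as.list(cand[best, ])
        pipe <- fit_pipeline(x[tr, , drop = FALSE], y[tr], prm)
        a <- auc(predict_pipeline(pipe, x[te, , drop = FALSE]), y[te])
        aucs <- c(aucs, a)
        imp <- pipe$fit$variable.importance
        full <- stats::setNames(numeric(length(feat_cols)), feat_cols)
        full[names(imp)] <- imp
        imp_sum <- imp_sum + full
        imp_n <- imp_n + 1L
        folds_tbl[[length(folds_tbl) + 1L]] <- tibble::tibble(
          rep = rep, fold = f, auc = a,
          num_trees = prm$num_trees, mtry_frac = prm$mtry_frac,
          min_node = prm$min_node, k = prm$k
        )
      }
    }
  })

  folds <- dplyr::bind_rows(folds_tbl)
  importance <- imp_sum / max(imp_n, 1L)
  if (sum(importance) > 0) importance <- importance / sum(importance)

  # final model: modal hyperparameters over outer folds, refit on all data
  sig <- paste(folds$num_trees, round(folds$mtry_frac, 3), folds$min_node, folds$k)
  modal <- folds[which(sig == names(sort(table(sig), decreasing = TRUE))[1L])[1L], ]
  final_params <- list(num_trees = modal$num_trees, mtry_frac = modal$mtry_frac,
                       min_node = modal$min_node, k = modal$k,
                       seed = config$seed)
  final_model <- with_seed(config$seed + 1L,
                           fit_pipeline(x, y, final_params))

  structure(
    list(auc = aucs, folds = folds, importance = importance,
         final_model = final_model, skipped = skipped, config = config,
         feature_names = feat_cols),
    class = "tbq_nested_cv"
  )
}

#' @export
print.tbq_nested_cv <- function(x, ...) {
  cat(sprintf(
    "<nested CV> %d outer AUC values (%d skipped): mean %.3f, sd %.3f\n",
    length(x$auc), x$skipped, mean(x$auc), stats::sd(x$auc)
  ))
  top <- sort(x$importance, decreasing = TRUE)[1:3]
  cat("top importances:",
      paste(sprintf("%s (%.0f%%)", names(top), 100 * top), collapse = ", "), "\n")
  invisible(x)
}

#' Mean Decrease Impurity importances of a nested CV run
#' @param x A `tbq_nested_cv`.
#' @return Tibble `feature`, `importance` (sums to 1), sorted descending.
#' @export
mdi_importance <- function(x) {
  stopifnot(inherits(x, "tbq_nested_cv"))
  tibble::tibble(feature = names(x$importance), importance = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Mann-Whitney comparison of two AUC samples
#'
#' Two-sided rank-sum test between, e.g., the outer-fold AUC distributions of
#' two models. Exact null distribution when the combined sample size is at
#' most 20 and there are no ties; tie-corrected normal approximation
#' otherwise. Outer folds are treated as independent samples, as is
#' conventional for this comparison (an optimistic assumption, documented
#' rather than corrected).
#'
#' @param a,b Numeric AUC samples.
#' @return Tibble: `statistic` (U of the first sample), `p_value`, `method`.
#' @export
compare_auc <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (length(unique(c(a, b))) == 1L) {
    # fully tied samples: no evidence of a shift
    return(tibble::tibble(statistic = length(a) * length(b) / 2,
                          p_value = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = !exact))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal")
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated two-sided bootstrap interval for a
#' statistic of a sample (default the mean, at the 99% level used for
#' reporting AUC uncertainty). Bias correction z0 comes from the bootstrap
#' distribution's position relative to the point estimate; acceleration from
#' jackknife skewness. A degenerate (all-equal) sample gives a point
#' interval.
#'
#' @param x Numeric sample (n >= 8 recommended).
#' @param statistic Function of a numeric vector, default `mean`.
#' @param level Confidence level, default 0.99.
#' @param B Bootstrap replicates, default 2000 (>= 1000 recommended).
#' @param seed RNG seed.
#' @return A `tbq_bca`: list with `estimate`, `lower`, `upper`, `level`, `B`.
#' @export
bca_ci <- function(x, statistic = mean, level = 0.99, B = 2000L, seed = 1L) {
  n <- length(x)
  theta <- statistic(x)
  if (all(x == x[1L])) {
    return(structure(list(estimate = theta, lower = theta, upper = theta,
                          level = level, B = 0L), class = "tbq_bca"))
  }
  with_seed(seed, {
    thetas <- vapply(seq_len(B), function(b) {
      statistic(x[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  z0 <- stats::qnorm((sum(thetas < theta) + 0.5 * sum(thetas == theta)) / B)
  z0 <- min(max(z0, -5), 5)
  jack <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  alpha <- (1 - level) / 2
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- unname(stats::quantile(thetas, adj))
  structure(
    list(estimate = theta, lower = min(ci[1L], theta),
         upper = max(ci[2L], theta), level = level, B = B),
    class = "tbq_bca"
  )
}

#' @export
print.tbq_bca <- function(x, ...) {
  cat(sprintf("<BCa %.0f%% CI> %.3f [%.3f, %.3f] (B = %d)\n",
              100 * x$level, x$estimate, x$lower, x$upper, x$B))
  invisible(x)
}

#' Run the experiment grid
#'
#' Nested cross-validation for each segmentation variant and each experiment
#' feature set, assembled into the familiar variants x experiments grid of
#' mean +/- SD outer AUC. For the richest feature set (Exp7) the variants are
#' additionally compared pairwise with two-sided Mann-Whitney tests on their
#' outer AUC distributions.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param variants Named list: variant label -> list(`quant_col`, `scheme`)
#'   where `scheme` is `"seven"` or `"four"` (a 7-class quantification is
#'   merged down for `"four"`). Default: the ground-truth 7-class
#'   quantification.
#' @param experiments Experiment ids (1..7 or "Exp1".."Exp7").
#' @param config A [cv_config()].
#' @return A `tbq_experiment_grid` tibble: `variant`, `experiment`,
#'   `mean_auc`, `sd_auc`, `n_folds`, `result` (list of `tbq_nested_cv`);
#'   attribute `"comparisons"` holds the pairwise Exp7 Mann-Whitney table.
#' @export
run_experiments <- function(cohort,
                            variants = list("seven-truth" = list(quant_col = "quant", scheme = "seven")),
                            experiments = 1:7,
                            config = cv_config()) {
  if (is.numeric(experiments)) experiments <- paste0("Exp", experiments)
  grid <- tidyr::expand_grid(variant = names(variants), experiment = experiments)
  res <- purrr::pmap(grid, function(variant, experiment) {
    v <- variants[[variant]]
    ft <- variant_feature_table(cohort, experiment, v)
    nested_cv(ft, config = config)
  })
  out <- dplyr::mutate(
    grid,
    mean_auc = vapply(res, function(r) mean(r$auc), numeric(1)),
    sd_auc = vapply(res, function(r) stats::sd(r$auc), numeric(1)),
    n_folds = vapply(res, function(r) length(r$auc), integer(1)),
    result = res
  )
  comps <- NULL
  if ("Exp7" %in% experiments && length(variants) > 1L) {
    e7 <- out[out$experiment == "Exp7", ]
    pairs <- utils::combn(e7$variant, 2L, simplify = FALSE)
    comps <- purrr::map_dfr(pairs, function(p) {
      a <- e7$result[[match(p[1L], e7$variant)]]$auc
      b <- e7$result[[match(p[2L], e7$variant)]]$auc
      dplyr::bind_cols(tibble::tibble(variant_a = p[1L], variant_b = p[2L]),
                       compare_auc(a, b))
    })
  }
  attr(out, "comparisons") <- comps
  class(out) <- c("tbq_experiment_grid", class(out))
  out
}

#' @noRd
variant_feature_table <- function(cohort, experiment, v) {
  qcol <- v$quant_col %||% "quant"
  if (identical(v$scheme, "four") && !experiment %in% c("Exp1", "Exp2")) {
    merged <- paste0(".", qcol, "_four")
    if (!merged %in% names(cohort)) {
      cohort[[merged]] <- purrr::map(cohort[[qcol]], merge_quant,
                                     target = scheme_four())
    }
    qcol <- merged
  }
  build_feature_table(cohort, exp = experiment, quant_col = qcol)
}

#' Apply a trained classification model to new patients
#'
#' Predicts `TILsum_High` probabilities with a model refit by [nested_cv()]
#' and measures accuracy against the observed outcome, reporting the raw
#' fraction (e.g. 5/6) alongside sensitivity and specificity. Feature names
#' and order must match the training manifest; a mismatch is a named error,
#' never silent reordering.
#'
#' @param model A `tbq_nested_cv` (its final refit model is used) or a
#'   `tbq_pipeline`.
#' @param data Feature table as from [build_feature_table()].
#' @param outcome,id Column names.
#' @param threshold Probability cut for the positive class, default 0.5.
#' @return Tibble: `accuracy`, `fraction`, `correct`, `total`,
#'   `sensitivity`, `specificity`; attribute `"predictions"` has per-patient
#'   probabilities.
#' @export
apply_model <- function(model, data, outcome = "label", id = "id",
                        threshold = 0.5) {
  pipe <- if (inherits(model, "tbq_nested_cv")) model$final_model else model
  stopifnot(inherits(pipe, "tbq_pipeline"))
  feat_cols <- setdiff(names(data), c(outcome, id))
  if (!identical(feat_cols, pipe$feature_names)) {
    miss <- setdiff(pipe$feature_names, feat_cols)
    extra <- setdiff(feat_cols, pipe$feature_names)
    stop("feature mismatch with the training manifest",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  p <- predict_pipeline(pipe, as.matrix(data[, feat_cols]))
  obs <- as_positive(data[[outcome]])
  pred <- p >= threshold
  correct <- sum(pred == obs)
  total <- length(obs)
  out <- tibble::tibble(
    accuracy = correct / total,
    fraction = sprintf("%d/%d", correct, total),
    correct = correct, total = total,
    sensitivity = if (any(obs)) sum(pred & obs) / sum(obs) else NA_real_,
    specificity = if (any(!obs)) sum(!pred & !obs) / sum(!obs) else NA_real_
  )
  attr(out, "predictions") <- tibble::tibble(
    id = as.character(data[[id]]), p_high = p, predicted = pred, observed = obs
  )
  out
}
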