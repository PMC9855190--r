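# Classifier bank: confusion-matrix metrics, cross-validated random
# hyper-parameter search, and grid evaluation over pipeline
# configurations.

#' Confusion-matrix performance metrics
#'
#' Computes specificity `TN / (FP + TN)`, sensitivity (recall)
#' `TP / (TP + FN)`, accuracy `(TP + TN) / (TP + TN + FP + FN)` and
#' balanced accuracy, the mean of sensitivity and specificity.
#'
#' @param tp,tn,fp,fn Non-negative confusion-matrix counts; both classes
#'   must be represented (`tp + fn >= 1`, `tn + fp >= 1`).
#' @return Named list with `specificity`, `sensitivity`, `accuracy`,
#'   `balanced_accuracy`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  for (v in list(tp, tn, fp, fn)) assert_scalar_number(v, "count", lower = 0)
  if (tp + fn < 1 || tn + fp < 1) {
    stop_dc("each class needs at least one true example (tp+fn=%g, tn+fp=%g)",
            tp + fn, tn + fp, class = "dynconn_value_error")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  list(specificity = spec, sensitivity = sens,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       balanced_accuracy = (sens + spec) / 2)
}

# Documented default random-search spaces.  `draw` maps a uniform deviate
# vector to one sampled configuration.
loguniform <- function(u, lo, hi) exp(log(lo) + u * (log(hi) - log(lo)))

sample_params <- function(name, n_iter) {
  # one draw per iteration; all randomness from the caller's seeded RNG
  draws <- vector("list", n_iter)
  for (k in seq_len(n_iter)) {
    draws[[k]] <- switch(name,
      lsvm = list(cost = loguniform(runif(1), 1e-3, 1e3)),
      lr   = list(cost = loguniform(runif(1), 1e-3, 1e3)),
      svm  = list(cost = loguniform(runif(1), 1e-3, 1e3),
                  gamma = loguniform(runif(1), 1e-4, 1e1)),
      rf   = list(ntree = sample(100:1000, 1L),
                  max_depth = sample(c(NA, 3:20), 1L)),
      lgbm = list(nrounds = 100L,
                  eta = loguniform(runif(1), 1e-3, 0.3),
                  num_leaves = sample(15:255, 1L)),
      nn   = list(size = sample(c(32L, 64L, 128L), 1L),
                  decay = loguniform(runif(1), 1e-5, 1e-1)),
      stop_dc("unknown classifier `%s`", name, class = "dynconn_value_error"))
  }
  draws
}

#' Classifier specification for random search
#'
#' @param name One of `"lsvm"`, `"lr"`, `"rf"`, `"lgbm"`, `"nn"`,
#'   `"svm"`.
#' @param n_iter Number of random configurations sampled (>= 1).
#' @param folds Stratified CV folds (default 5).
#' @param seed Integer seed for sampling and fold assignment.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, n_iter = 50, folds = 5, seed = 1) {
  name <- match.arg(name, CLASSIFIER_LEVELS)
  assert_scalar_number(n_iter, "n_iter", lower = 1)
  assert_scalar_number(folds, "folds", lower = 2)
  structure(list(name = name, n_iter = as.integer(n_iter),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Cross-validated random hyper-parameter search
#'
#' Samples `n_iter` configurations from the classifier's documented search
#' space, scores each by stratified k-fold mean balanced accuracy (features
#' standardised with train-fold statistics for scale-sensitive
#' classifiers), and returns the best configuration with its per-fold
#' metrics.  Ties go to the first-sampled configuration.  Deterministic
#' given `spec$seed`.
#'
#' @param X Numeric matrix or `feature_matrix` of (already selected)
#'   features; when `nested_selection` is given, the *full* (unselected)
#'   matrix.
#' @param y Binary labels.
#' @param spec A [classifier_spec()].
#' @param nested_selection Optional [selection_config()]: when supplied,
#'   the two-stage feature selection is rerun inside every training fold
#'   and the held-out fold is scored on that fold's own selected features,
#'   eliminating selection leakage from the reported scores (the
#'   selection is shared across sampled hyper-parameter configurations).
#' @return Object of class `classifier_result`: `name`, `best_params`,
#'   `fold_scores` (data.frame: accuracy, sensitivity, specificity,
#'   balanced_accuracy per fold), `mean_std` (per-metric mean and sd),
#'   `search_scores` (mean balanced accuracy of every sampled
#'   configuration), `seed`.
#' @export
random_search_cv <- function(X, y, spec, nested_selection = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  vals <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (any(!is.finite(vals))) {
    stop_dc("non-finite feature values", class = "dynconn_value_error")
  }
  y <- as_binary_factor(y)
  if (nrow(vals) < spec$folds) {
    stop_dc("%d samples < %d folds", nrow(vals), spec$folds,
            class = "dynconn_value_error")
  }
  fold <- stratified_folds(y, spec$folds, derive_seed(spec$seed, "search-folds"))
  cols_by_fold <- NULL
  if (!is.null(nested_selection)) {
    stopifnot(inherits(nested_selection, "selection_config"))
    if (is.null(colnames(vals))) {
      colnames(vals) <- sprintf("f%04d", seq_len(ncol(vals)))
    }
    cols_by_fold <- lapply(seq_len(spec$folds), function(f) {
      cfg <- nested_selection
      cfg$seed <- derive_seed(spec$seed, paste0("nested-sel/", f))
      select_features(vals[fold != f, , drop = FALSE], y[fold != f],
                      cfg)$selected_names
    })
  }
  draws <- with_seed(derive_seed(spec$seed, paste0("search/", spec$name)),
                     sample_params(spec$name, spec$n_iter))
  scores <- vapply(seq_along(draws), function(k) {
    cv_balanced_accuracy(spec$name, vals, y, fold, draws[[k]],
                         seed = derive_seed(spec$seed, paste0("eval/", k)),
                         cols_by_fold = cols_by_fold)
  }, numeric(1))
  best_k <- which.max(scores)            # ties -> first sampled
  per_fold <- cv_balanced_accuracy(spec$name, vals, y, fold, draws[[best_k]],
                                   seed = derive_seed(spec$seed,
                                                      paste0("eval/", best_k)),
                                   per_fold = TRUE,
                                   cols_by_fold = cols_by_fold)
  fold_scores <- as.data.frame(per_fold)
  mean_std <- lapply(fold_scores, function(col) c(mean = mean(col), sd = sd(col)))
  structure(
    list(name = spec$name, best_params = draws[[best_k]],
         fold_scores = fold_scores, mean_std = mean_std,
         search_scores = scores, seed = spec$seed),
    class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> %s: balanced accuracy %.3f +/- %.3f (%d folds)\n",
              x$name, x$mean_std$balanced_accuracy[["mean"]],
              x$mean_std$balanced_accuracy[["sd"]], nrow(x$fold_scores)))
  invisible(x)
}

#' Evaluate classifier bank over selected feature sets
#'
#' The workhorse behind the configuration grid: for every supplied
#' (feature matrix, selection result) pair and every classifier, restricts
#' the matrix to the selected features, runs [random_search_cv()], and
#' appends one row (representation, atlas, strategy, kernel, classifier,
#' mean/sd of each metric, n features, seed) to the long-format results
#' table.
#'
#' Rows are checkpointed to `checkpoint_path` (CSV) as they complete; an
#' existing checkpoint is resumed, skipping configurations already
#' evaluated.
#'
#' @param feature_matrices List of `feature_matrix` objects.
#' @param selections List (parallel to `feature_matrices`) of *lists of*
#'   `selection_result`s, one per RFE kernel.  A [selection_config()] may
#'   stand in for a result, in which case that cell is evaluated in nested
#'   mode: selection is rerun inside every training fold (see
#'   [random_search_cv()]'s `nested_selection`).
#' @param classifiers Character vector of classifier names.
#' @param y Binary labels shared by all matrices.
#' @param n_iter,folds Passed to [classifier_spec()].
#' @param seed Master seed; per-cell seeds are derived from it so the
#'   evaluation fold split is fresh (distinct from selection folds).
#' @param checkpoint_path Optional CSV path for incremental results.
#' @return Long-format results `data.frame` (a configuration results
#'   table, see [write_results_table()]).
#' @export
evaluate_all <- function(feature_matrices, selections, y,
                         classifiers = CLASSIFIER_LEVELS, n_iter = 50,
                         folds = 5, seed = 1, checkpoint_path = NULL) {
  stopifnot(length(feature_matrices) == length(selections))
  classifiers <- match.arg(classifiers, CLASSIFIER_LEVELS, several.ok = TRUE)
  done <- NULL
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    done <- read_results_table(checkpoint_path)
  }
  rows <- if (is.null(done)) list() else list(done)
  have <- function(rep, atl, strat, ker, cls) {
    !is.null(done) && any(done$representation == rep & done$atlas == atl &
                            done$strategy == strat & done$kernel == ker &
                            done$classifier == cls)
  }
  for (m in seq_along(feature_matrices)) {
    fm <- feature_matrices[[m]]
    stopifnot(inherits(fm, "feature_matrix"))
    sel_list <- selections[[m]]
    if (inherits(sel_list, "selection_result")) sel_list <- list(sel_list)
    for (sel in sel_list) {
      nested <- inherits(sel, "selection_config")
      if (nested) {
        Xsel <- fm$values
      } else {
        missing <- setdiff(sel$selected_names, fm$feature_names)
        if (length(missing) > 0L) {
          stop_dc("selection (%s) names %d feature(s) absent from the %s matrix",
                  sel$kernel, length(missing), fm$representation,
                  class = "dynconn_schema_error")
        }
        Xsel <- fm$values[, sel$selected_names, drop = FALSE]
      }
      for (cls in classifiers) {
        if (have(fm$representation, fm$atlas_tag, fm$strategy_tag,
                 sel$kernel, cls)) next
        cell_seed <- derive_seed(seed, paste("cell", fm$representation,
                                             fm$atlas_tag, fm$strategy_tag,
                                             sel$kernel, cls, sep = "/"))
        res <- random_search_cv(Xsel, y,
                                classifier_spec(cls, n_iter = n_iter,
                                                folds = folds,
                                                seed = cell_seed),
                                nested_selection = if (nested) sel)
        row <- data.frame(
          representation = fm$representation, atlas = fm$atlas_tag,
          strategy = fm$strategy_tag, kernel = sel$kernel, classifier = cls,
          score = res$mean_std$balanced_accuracy[["mean"]],
          score_sd = res$mean_std$balanced_accuracy[["sd"]],
          accuracy = res$mean_std$accuracy[["mean"]],
          sensitivity = res$mean_std$sensitivity[["mean"]],
          specificity = res$mean_std$specificity[["mean"]],
          n_features = if (nested) NA_integer_ else length(sel$selected_names),
          seed = seed, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- row
        if (!is.null(checkpoint_path)) {
          write_results_table(do.call(rbind, rows), checkpoint_path)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_results_table(out)
  out
}
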