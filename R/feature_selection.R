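# Two-stage feature selection: univariate ANOVA-F filter, then recursive
# feature elimination scored by stratified k-fold balanced accuracy.

#' Selection configuration
#'
#' @param kernel RFE elimination kernel: `"lsvm"`, `"lr"`, `"rf"` or
#'   `"lgbm"`.
#' @param univariate_proportion Proportion of features kept by the
#'   univariate ANOVA-F stage, in (0, 1].
#' @param rfe_step Features removed per elimination round (>= 1).
#' @param folds Number of stratified CV folds (>= 2).
#' @param seed Integer seed controlling fold assignment and kernel fits.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(kernel = "lsvm", univariate_proportion = 0.25,
                             rfe_step = 2, folds = 5, seed = 1) {
  kernel <- match.arg(kernel, KERNEL_LEVELS)
  assert_scalar_number(univariate_proportion, "univariate_proportion",
                       lower = 1e-12, upper = 1)
  assert_scalar_number(rfe_step, "rfe_step", lower = 1)
  assert_scalar_number(folds, "folds", lower = 2)
  structure(list(kernel = kernel,
                 univariate_proportion = univariate_proportion,
                 rfe_step = as.integer(rfe_step), folds = as.integer(folds),
                 scoring = "balanced_accuracy", seed = as.integer(seed)),
            class = "selection_config")
}

#' Two-group ANOVA F statistics per feature
#'
#' The classical one-way F score of each feature against the binary label
#' (equal to the squared two-sample t statistic).  Constant features get
#' F = 0.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Binary labels.
#' @return Numeric vector of F values (one per column of `X`).
#' @export
anova_f_scores <- function(X, y) {
  y <- as_binary_factor(y)
  X <- as.matrix(X)
  g1 <- y == levels(y)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  m <- colMeans(X)
  ss_between <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ss_within <- colSums((X[g1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((X[!g1, , drop = FALSE] - rep(m2, each = n2))^2)
  f <- (ss_between / 1) / (ss_within / (n1 + n2 - 2))
  f[ss_between == 0] <- 0                # constant or identical-mean feature
  f[ss_within == 0 & ss_between > 0] <- Inf
  unname(f)
}

#' Univariate ANOVA-F feature filter
#'
#' Keeps the `ceiling(proportion * n_features)` features with the largest
#' two-group F statistic; ties are broken by original column order.
#'
#' @param X A `feature_matrix` (see [build_feature_matrix()]) or plain
#'   numeric matrix with column names.
#' @param y Binary labels (two classes required).
#' @param proportion Proportion of features to keep, in (0, 1].
#' @return Object of the same type as `X`, reduced to the surviving
#'   columns (order preserved).
#' @export
univariate_f_select <- function(X, y, proportion = 0.25) {
  assert_scalar_number(proportion, "proportion", lower = 1e-12, upper = 1)
  vals <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  f <- anova_f_scores(vals, y)
  n_keep <- ceiling(proportion * ncol(vals))
  # stable selection: order by decreasing F, ties by column position
  keep <- sort(order(-f, seq_along(f))[seq_len(n_keep)])
  if (inherits(X, "feature_matrix")) {
    X$values <- X$values[, keep, drop = FALSE]
    X$feature_names <- colnames(X$values)
    X
  } else {
    vals[, keep, drop = FALSE]
  }
}

# One recursive-elimination pass on (vals, y): fit the kernel on the
# surviving features, drop the `step` weakest, repeat down to one feature.
# Returns the ranking (strongest first) and, when `test` is supplied, the
# test-split balanced accuracy recorded at every candidate size.
rfe_eliminate <- function(kernel, vals, y, step, seed_base, salt,
                          test_vals = NULL, test_y = NULL) {
  surviving <- colnames(vals)
  eliminated <- character(0)             # worst first
  counts <- integer(0)
  scores <- numeric(0)
  sp <- if (needs_scaling(kernel)) scale_params(vals) else NULL
  pos <- positive_level(y)
  round_i <- 0L
  repeat {
    counts <- c(counts, length(surviving))
    round_i <- round_i + 1L
    Xs <- vals[, surviving, drop = FALSE]
    Xt <- if (!is.null(test_vals)) test_vals[, surviving, drop = FALSE]
    if (!is.null(sp)) {
      sps <- list(mu = sp$mu[surviving], sg = sp$sg[surviving])
      Xs <- apply_scale(Xs, sps)
      if (!is.null(Xt)) Xt <- apply_scale(Xt, sps)
    }
    model <- tryCatch(
      fit_kernel(kernel, Xs, y,
                 seed = derive_seed(seed_base, paste0(salt, "/", round_i))),
      error = function(e) {
        stop_dc("kernel `%s` failed at elimination round %d: %s", kernel,
                round_i, conditionMessage(e), class = "dynconn_fit_error")
      })
    if (!is.null(Xt)) {
      pred <- predict_kernel(model, Xt)
      scores <- c(scores, balanced_accuracy_score(test_y, pred, pos))
    }
    if (length(surviving) == 1L) break
    imp <- kernel_importance(model)
    n_drop <- min(step, length(surviving) - 1L)
    # drop the weakest features; ties broken by current order for determinism
    drop_idx <- order(imp, seq_along(imp))[seq_len(n_drop)]
    eliminated <- c(surviving[drop_idx], eliminated)
    surviving <- surviving[-drop_idx]
  }
  list(ranking = c(surviving, eliminated), counts = counts, scores = scores)
}

#' Recursive feature elimination with cross-validation
#'
#' For each of the k stratified folds, features are recursively eliminated
#' on the training split alone (the kernel is fit on the survivors and the
#' `rfe_step` lowest-importance features dropped per round) while the
#' held-out fold is scored at every candidate feature count; the count
#' with the best mean balanced accuracy across folds wins (ties go to the
#' smaller count).  The final selected set is the top of an elimination
#' ranking recomputed on the full data at the winning count.  Eliminating
#' within each training split keeps the reported cross-validated scores
#' free of selection leakage.
#'
#' @param X A `feature_matrix` or numeric matrix (already reduced by
#'   [univariate_f_select()] in the standard cascade).
#' @param y Binary labels.
#' @param config A [selection_config()].
#' @return Object of class `selection_result`: `kernel`,
#'   `selected_names`, `cv_score_by_count` (named vector,
#'   names = candidate counts), `best_score`, `best_count`, `ranking`
#'   (full-data elimination order, best first), `seed`.
#' @export
rfe_cv <- function(X, y, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  vals <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (is.null(colnames(vals))) {
    colnames(vals) <- sprintf("f%04d", seq_len(ncol(vals)))
  }
  y <- as_binary_factor(y)
  p <- ncol(vals)
  if (p < config$rfe_step) {
    stop_dc("need at least rfe_step = %d features (got %d)", config$rfe_step,
            p, class = "dynconn_value_error")
  }

  fold <- stratified_folds(y, config$folds, derive_seed(config$seed, "rfe-folds"))
  k <- max(fold)
  score_by_fold <- NULL
  for (f in seq_len(k)) {
    tr <- fold != f
    path <- rfe_eliminate(config$kernel, vals[tr, , drop = FALSE], y[tr],
                          config$rfe_step, config$seed, paste0("rfe-fold", f),
                          test_vals = vals[!tr, , drop = FALSE],
                          test_y = y[!tr])
    if (is.null(score_by_fold)) {
      score_by_fold <- matrix(NA_real_, length(path$counts), k,
                              dimnames = list(as.character(path$counts), NULL))
    }
    score_by_fold[, f] <- path$scores
  }
  counts <- as.integer(rownames(score_by_fold))
  cv_scores <- rowMeans(score_by_fold)
  names(cv_scores) <- as.character(counts)

  best <- max(cv_scores)
  # ties -> smallest feature count (counts are recorded descending)
  best_count <- min(counts[cv_scores >= best - 1e-15])

  full_path <- rfe_eliminate(config$kernel, vals, y, config$rfe_step,
                             config$seed, "rfe-full")
  structure(
    list(kernel = config$kernel,
         selected_names = full_path$ranking[seq_len(best_count)],
         cv_score_by_count = cv_scores,
         best_score = best,
         best_count = best_count,
         ranking = full_path$ranking,
         seed = config$seed),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> kernel %s: %d features selected, CV balanced accuracy %.3f\n",
              x$kernel, x$best_count, x$best_score))
  invisible(x)
}

#' Run the two-stage selection cascade
#'
#' [univariate_f_select()] followed by [rfe_cv()].
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param y Binary labels.
#' @param config A [selection_config()].
#' @return A `selection_result` (see [rfe_cv()]); the univariate survivors
#'   are recorded in `$univariate_names`.
#' @export
select_features <- function(X, y, config = selection_config()) {
  reduced <- univariate_f_select(X, y, config$univariate_proportion)
  res <- rfe_cv(reduced, y, config)
  res$univariate_names <-
    if (inherits(reduced, "feature_matrix")) reduced$feature_names
    else colnames(reduced)
  res
}

#' Run selection under several RFE kernels with shared folds
#'
#' One [select_features()] call per kernel, all sharing `config`'s seed so
#' the stratified folds are identical across kernels and the results are
#' comparable.
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param y Binary labels.
#' @param kernels Character vector of RFE kernels.
#' @param config A [selection_config()] (its `kernel` field is overridden
#'   per run).
#' @return Named list of `selection_result`s.
#' @export
run_selection_grid <- function(X, y, kernels = KERNEL_LEVELS,
                               config = selection_config()) {
  kernels <- match.arg(kernels, KERNEL_LEVELS, several.ok = TRUE)
  res <- lapply(kernels, function(k) {
    cfg <- config
    cfg$kernel <- k
    select_features(X, y, cfg)
  })
  names(res) <- kernels
  res
}

#' Write a selection result as JSON plus a plain-text feature list
#'
#' @param result A `selection_result`.
#' @param json_path JSON output path (`NULL` to skip).
#' @param names_path Plain-text output path, one selected feature name per
#'   line (`NULL` to skip).
#' @return `result`, invisibly.
#' @export
write_selection_result <- function(result, json_path = NULL, names_path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(kernel = result$kernel, selected_names = result$selected_names,
           cv_score_by_count = as.list(result$cv_score_by_count),
           best_score = result$best_score, best_count = result$best_count,
           seed = result$seed),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(names_path)) {
    writeLines(result$selected_names, names_path)
  }
  invisible(result)
}
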