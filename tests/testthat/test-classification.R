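test_that("confusion metrics follow the standard formulas", {
  m <- confusion_metrics(tp = 987, tn = 989, fp = 11, fn = 13)
  expect_equal(m$sensitivity, 0.987)
  expect_equal(m$specificity, 0.989)
  expect_equal(m$balanced_accuracy, 0.988)

  all1 <- confusion_metrics(50, 50, 0, 0)
  expect_equal(unlist(all1), c(specificity = 1, sensitivity = 1,
                               accuracy = 1, balanced_accuracy = 1))

  # all-positive predictor on 30 pos / 70 neg
  ap <- confusion_metrics(tp = 30, tn = 0, fp = 70, fn = 0)
  expect_equal(ap$sensitivity, 1)
  expect_equal(ap$specificity, 0)
  expect_equal(ap$balanced_accuracy, 0.5)

  expect_error(confusion_metrics(0, 10, 5, 0), class = "dynconn_value_error")
})

test_that("random search achieves perfect accuracy on separable data", {
  set.seed(5)
  n <- 40
  X <- matrix(rnorm(n * 4), n)
  colnames(X) <- paste0("f", 1:4)
  X[1:(n / 2), 1] <- X[1:(n / 2), 1] + 8
  y <- factor(rep(c("ASD", "TD"), each = n / 2), levels = c("TD", "ASD"))
  res <- random_search_cv(X, y, classifier_spec("lsvm", n_iter = 5, folds = 5,
                                                seed = 3))
  expect_equal(res$mean_std$balanced_accuracy[["mean"]], 1.0)
})

test_that("random search is deterministic and keeps honest books", {
  pm <- planted_matrix(n_per_group = 20, n_signal = 2, n_noise = 6, seed = 44)
  for (cls in c("lsvm", "lr", "rf", "lgbm", "nn", "svm")) {
    spec <- classifier_spec(cls, n_iter = 3, folds = 4, seed = 17)
    a <- random_search_cv(pm$X, pm$y, spec)
    b <- random_search_cv(pm$X, pm$y, spec)
    expect_identical(a$best_params, b$best_params, label = cls)
    expect_identical(a$fold_scores, b$fold_scores, label = cls)
    # per-fold identity: balanced accuracy == mean(sensitivity, specificity)
    expect_equal(a$fold_scores$balanced_accuracy,
                 (a$fold_scores$sensitivity + a$fold_scores$specificity) / 2,
                 tolerance = 1e-12)
    # the winning score is reproduced by re-evaluating best_params directly
    fold <- dynconn:::stratified_folds(
      pm$y, 4, dynconn:::derive_seed(17, "search-folds"))
    k <- which.max(a$search_scores)
    redo <- dynconn:::cv_balanced_accuracy(
      cls, pm$X, pm$y, fold, a$best_params,
      seed = dynconn:::derive_seed(17, paste0("eval/", k)))
    expect_equal(redo, mean(a$fold_scores$balanced_accuracy),
                 tolerance = 1e-12, label = cls)
  }
})

test_that("non-finite features are rejected", {
  pm <- planted_matrix(n_per_group = 10, n_signal = 1, n_noise = 3, seed = 2)
  pm$X[1, 1] <- NA
  expect_error(random_search_cv(pm$X, pm$y, classifier_spec("lsvm")),
               class = "dynconn_value_error")
})

test_that("evaluate_all produces the configuration grid row-set", {
  coh <- simulate_cohort(10, 10, state_model(6, 0.95),
                         group_effect(data.frame(i = 1, j = 2), 0.9, 0.1),
                         length_tr = 100, seed = 6)
  y <- cohort_labels(coh)
  fms <- list(build_feature_matrix(coh, "FC"), build_feature_matrix(coh, "dFC"))
  sels <- lapply(fms, function(fm) {
    run_selection_grid(fm, y, kernels = c("lsvm", "rf"),
                       config = selection_config(univariate_proportion = 0.5,
                                                 folds = 5, seed = 4))
  })
  tab <- evaluate_all(fms, sels, y, classifiers = c("lsvm", "lr"),
                      n_iter = 2, folds = 5, seed = 10)
  # 2 representations x 2 kernels x 2 classifiers
  expect_identical(nrow(tab), 8L)
  expect_setequal(unique(tab$representation), c("FC", "dFC"))
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  expect_equal(tab$score, (tab$sensitivity + tab$specificity) / 2,
               tolerance = 1e-12)
})

test_that("checkpointed evaluation resumes to the same table as a cold run", {
  coh <- simulate_cohort(8, 8, state_model(4, 0.9),
                         group_effect(data.frame(i = 1, j = 2), 0.85, 0.15),
                         length_tr = 80, seed = 3)
  y <- cohort_labels(coh)
  fm <- build_feature_matrix(coh, "FC")
  sel <- select_features(fm, y, selection_config(univariate_proportion = 1,
                                                 folds = 4, seed = 2))
  cold <- evaluate_all(list(fm), list(list(sel)), y,
                       classifiers = c("lsvm", "lr"), n_iter = 2, folds = 4,
                       seed = 5)
  ck <- withr::local_tempfile(fileext = ".csv")
  first <- evaluate_all(list(fm), list(list(sel)), y,
                        classifiers = "lsvm", n_iter = 2, folds = 4,
                        seed = 5, checkpoint_path = ck)
  resumed <- evaluate_all(list(fm), list(list(sel)), y,
                          classifiers = c("lsvm", "lr"), n_iter = 2,
                          folds = 4, seed = 5, checkpoint_path = ck)
  cmp <- function(t) t[order(t$classifier), c("classifier", "score", "score_sd")]
  expect_equal(cmp(resumed), cmp(cold), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("null-label calibration keeps all classifiers near chance", {
  set.seed(123)
  n <- 100
  X <- matrix(rnorm(n * 10), n)
  colnames(X) <- sprintf("f%02d", 1:10)
  y <- factor(sample(rep(c("ASD", "TD"), each = n / 2)), levels = c("TD", "ASD"))
  scores <- vapply(c("lsvm", "lr", "rf", "lgbm", "nn", "svm"), function(cls) {
    res <- random_search_cv(X, y, classifier_spec(cls, n_iter = 4, folds = 5,
                                                  seed = 31))
    res$mean_std$balanced_accuracy[["mean"]]
  }, numeric(1))
  expect_true(all(scores >= 0.35 & scores <= 0.65))
})
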