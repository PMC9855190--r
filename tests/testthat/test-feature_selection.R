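test_that("univariate F filter keeps label-aligned features and drops constants", {
  set.seed(20)
  n <- 60
  y <- factor(rep(c("ASD", "TD"), each = n / 2), levels = c("TD", "ASD"))
  X <- matrix(rnorm(n * 50), n)
  colnames(X) <- sprintf("noise%02d", 1:50)
  X <- cbind(X, label_copy = as.numeric(y == "ASD"))
  red <- univariate_f_select(X, y, proportion = 0.1)
  expect_true("label_copy" %in% colnames(red))

  Xc <- cbind(X[, 1:10], const = 1)
  red2 <- univariate_f_select(Xc, y, proportion = 0.5)
  expect_false("const" %in% colnames(red2))

  expect_error(univariate_f_select(X, factor(rep("ASD", n))),
               class = "dynconn_value_error")
})

test_that("mean-shifted features survive the univariate filter across seeds", {
  hits <- vapply(1:20, function(s) {
    pm <- planted_matrix(n_per_group = 50, n_signal = 5, n_noise = 200,
                         delta = 2, seed = 300 + s)
    kept <- colnames(univariate_f_select(pm$X, pm$y, proportion = 0.05))
    all(sprintf("sig%02d", 1:5) %in% kept)
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("univariate F of existing features is unchanged by appended noise", {
  pm <- planted_matrix(seed = 31)
  f1 <- anova_f_scores(pm$X, pm$y)
  set.seed(99)
  extra <- matrix(rnorm(nrow(pm$X) * 30), nrow(pm$X))
  f2 <- anova_f_scores(cbind(pm$X, extra), pm$y)
  expect_identical(f1, f2[seq_along(f1)])
})

test_that("RFE recovers a label-identical column with perfect score", {
  set.seed(7)
  n <- 40
  y <- factor(rep(c("ASD", "TD"), each = n / 2), levels = c("TD", "ASD"))
  X <- cbind(matrix(rnorm(n * 7), n), as.numeric(y == "ASD"))
  colnames(X) <- c(sprintf("n%d", 1:7), "the_label")
  for (k in c("lsvm", "lr", "rf", "lgbm")) {
    res <- rfe_cv(X, y, selection_config(k, folds = 5, seed = 13))
    expect_true("the_label" %in% res$selected_names, label = k)
    expect_equal(res$best_score, 1.0, tolerance = 1e-12)
  }
})

test_that("pure-noise RFE scores stay near chance", {
  scores <- vapply(1:20, function(s) {
    set.seed(600 + s)
    n <- 100
    X <- matrix(rnorm(n * 20), n)
    colnames(X) <- sprintf("f%02d", 1:20)
    y <- factor(rep(c("ASD", "TD"), each = n / 2), levels = c("TD", "ASD"))
    rfe_cv(X, y, selection_config("lsvm", folds = 5,
                                  seed = 600 + s))$best_score
  }, numeric(1))
  # best_score is a max over candidate counts, so it sits slightly above 0.5
  expect_lt(abs(mean(scores) - 0.5), 0.15)
  expect_true(all(scores < 0.75))
})

test_that("RFE is competitive with the exhaustive best subset under shared folds", {
  for (s in 1:3) {
    pm <- planted_matrix(n_per_group = 20, n_signal = 2, n_noise = 4,
                         delta = 1.5, seed = 70 + s)
    cfg <- selection_config("lsvm", folds = 5, seed = 70 + s)
    res <- rfe_cv(pm$X, pm$y, cfg)
    fold <- dynconn:::stratified_folds(pm$y, 5,
                                       dynconn:::derive_seed(70 + s, "rfe-folds"))
    subsets <- unlist(lapply(1:6, function(k) {
      combn(colnames(pm$X), k, simplify = FALSE)
    }), recursive = FALSE)
    exhaustive <- vapply(subsets, function(cols) {
      lsvm_cv_oracle(pm$X, pm$y, cols, fold)
    }, numeric(1))
    rfe_subset_score <- lsvm_cv_oracle(pm$X, pm$y, res$selected_names, fold)
    expect_gte(rfe_subset_score, max(exhaustive) - 0.1)
  }
})

test_that("the cascade is deterministic and selects within the univariate survivors", {
  pm <- planted_matrix(n_per_group = 25, n_signal = 3, n_noise = 40, seed = 8)
  cfg <- selection_config("lsvm", univariate_proportion = 0.3, folds = 5,
                          seed = 21)
  a <- select_features(pm$X, pm$y, cfg)
  b <- select_features(pm$X, pm$y, cfg)
  expect_identical(a$selected_names, b$selected_names)
  expect_identical(a$cv_score_by_count, b$cv_score_by_count)
  expect_true(all(a$selected_names %in% a$univariate_names))
  expect_equal(a$best_score, max(a$cv_score_by_count))
})

test_that("the kernel grid shares folds and finds planted signal everywhere", {
  pm <- planted_matrix(n_per_group = 25, n_signal = 3, n_noise = 17,
                       delta = 2, seed = 14)
  cfg <- selection_config(univariate_proportion = 1, folds = 5, seed = 5)
  grid <- run_selection_grid(pm$X, pm$y, config = cfg)
  expect_identical(names(grid), c("lsvm", "lr", "rf", "lgbm"))
  for (k in names(grid)) {
    expect_true(any(grepl("^sig", grid[[k]]$selected_names)), label = k)
  }
  grid2 <- run_selection_grid(pm$X, pm$y, config = cfg)
  expect_identical(lapply(grid, `[[`, "selected_names"),
                   lapply(grid2, `[[`, "selected_names"))
})

test_that("selection results serialise to JSON and a name list", {
  pm <- planted_matrix(n_per_group = 15, n_signal = 2, n_noise = 6, seed = 3)
  res <- select_features(pm$X, pm$y,
                         selection_config("lsvm", univariate_proportion = 1,
                                          folds = 3, seed = 2))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".txt")
  write_selection_result(res, jf, tf)
  j <- jsonlite::read_json(jf)
  expect_identical(unlist(j$selected_names), res$selected_names)
  expect_identical(readLines(tf), res$selected_names)
})
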