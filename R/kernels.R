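# Unified interface over the classifier kernels (fit / predict /
# feature-importance) used both as RFE elimination kernels and as the
# final classifier bank.  Backends: e1071 (linear and RBF SVM), glmnet
# (ridge-penalised logistic regression), randomForest, xgboost
# (histogram-based gradient-boosted trees), nnet (single-hidden-layer
# perceptron with L2 decay).

POSITIVE_CLASS <- "ASD"

as_binary_factor <- function(y) {
  if (is.factor(y)) {
    y <- droplevels(y)
    if (nlevels(y) == 1L) {
      stop_dc("labels contain a single class (%s)", levels(y),
              class = "dynconn_value_error")
    }
    if (nlevels(y) != 2L) {
      stop_dc("labels must be binary (got %d levels)", nlevels(y),
              class = "dynconn_value_error")
    }
    if (all(levels(y) %in% c("TD", "ASD"))) {
      return(factor(as.character(y), levels = c("TD", "ASD")))
    }
    return(y)
  }
  u <- sort(unique(as.character(y)))
  if (length(u) != 2L) {
    stop_dc("labels must be binary (got %d distinct values)", length(u),
            class = "dynconn_value_error")
  }
  if (all(u %in% c("TD", "ASD"))) u <- c("TD", "ASD")
  factor(as.character(y), levels = u)
}

positive_level <- function(y) {
  if (POSITIVE_CLASS %in% levels(y)) POSITIVE_CLASS else levels(y)[2L]
}

# Default hyper-parameters used when a kernel is fit outside random search
# (e.g. during RFE elimination).
default_kernel_params <- function(name) {
  switch(name,
    lsvm = list(cost = 1),
    svm  = list(cost = 1, gamma = NA),   # NA -> 1/p at fit time
    lr   = list(cost = 1),
    rf   = list(ntree = 300, max_depth = NA),
    lgbm = list(nrounds = 100, eta = 0.1, num_leaves = 31),
    nn   = list(size = 32, decay = 1e-3),
    stop_dc("unknown kernel `%s`", name, class = "dynconn_value_error"))
}

needs_scaling <- function(name) name %in% c("lsvm", "svm", "lr", "nn")

# Train-set standardisation parameters; constant columns get sd 1 so they
# map to 0 rather than NaN.
scale_params <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2L, sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(mu = mu, sg = sg)
}

apply_scale <- function(X, sp) {
  sweep(sweep(X, 2L, sp$mu, `-`), 2L, sp$sg, `/`)
}

fit_kernel <- function(name, X, y, params = NULL, seed = 1) {
  y <- as_binary_factor(y)
  params <- modifyList(default_kernel_params(name), params %||% list())
  X <- as.matrix(X)
  if (any(!is.finite(X))) {
    stop_dc("non-finite feature values passed to kernel `%s`", name,
            class = "dynconn_value_error")
  }
  fit <- with_seed(seed, switch(name,
    lsvm = e1071::svm(X, y, kernel = "linear", cost = params$cost,
                      scale = FALSE),
    svm = {
      g <- params$gamma
      if (is.na(g)) g <- 1 / ncol(X)
      e1071::svm(X, y, kernel = "radial", cost = params$cost, gamma = g,
                 scale = FALSE)
    },
    lr = {
      n <- nrow(X)
      lambda <- 1 / (n * params$cost)
      # glmnet needs >= 2 columns; pad a constant that gets no weight
      Xg <- if (ncol(X) == 1L) cbind(X, `..const` = 0) else X
      # glmnet warns about tiny classes on every fit; that is a property
      # of the fold size, not a fault worth repeating per fold
      withCallingHandlers(
        glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                       lambda = lambda, standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    },
    rf = {
      maxnodes <- if (is.na(params$max_depth)) NULL
                  else max(2L, min(2L^params$max_depth, nrow(X)))
      randomForest::randomForest(X, y, ntree = params$ntree,
                                 maxnodes = maxnodes)
    },
    lgbm = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y == positive_level(y)))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", tree_method = "hist",
                      grow_policy = "lossguide", max_depth = 0,
                      max_leaves = params$num_leaves, eta = params$eta,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    nn = {
      nwts <- (ncol(X) + 1L) * params$size + (params$size + 1L)
      nnet::nnet(X, class.ind2(y), size = params$size, decay = params$decay,
                 maxit = 200, trace = FALSE, MaxNWts = max(nwts + 1L, 10000L),
                 softmax = TRUE)
    },
    stop_dc("unknown kernel `%s`", name, class = "dynconn_value_error")))
  structure(list(name = name, fit = fit, params = params,
                 levels = levels(y), positive = positive_level(y),
                 feature_names = colnames(X)),
            class = "dynconn_kernel_fit")
}

# two-column class indicator in level order, for nnet's softmax interface
class.ind2 <- function(y) {
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

predict_kernel <- function(model, X) {
  X <- as.matrix(X)
  lev <- model$levels
  out <- switch(model$name,
    lsvm = ,
    svm = as.character(predict(model$fit, X)),
    lr = {
      Xg <- if (ncol(X) == 1L) cbind(X, `..const` = 0) else X
      as.character(predict(model$fit, Xg, type = "class"))
    },
    rf = as.character(predict(model$fit, X)),
    lgbm = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(X))
      ifelse(p > 0.5, model$positive, setdiff(lev, model$positive))
    },
    nn = {
      p <- predict(model$fit, X)
      lev[max.col(p, ties.method = "first")]
    })
  factor(out, levels = lev)
}

# Per-feature importance used by RFE: |weight| for the linear kernels,
# impurity importance for the tree kernels.
kernel_importance <- function(model) {
  imp <- switch(model$name,
    lsvm = {
      w <- drop(crossprod(model$fit$coefs, model$fit$SV))
      abs(w)
    },
    lr = {
      cf <- as.matrix(coef(model$fit))[-1L, 1L]
      cf <- cf[names(cf) != "..const"]
      abs(cf)
    },
    rf = drop(randomForest::importance(model$fit)[, 1L]),
    lgbm = {
      tab <- xgboost::xgb.importance(model = model$fit)
      imp <- setNames(numeric(length(model$feature_names)), model$feature_names)
      if (!is.null(tab) && nrow(tab) > 0L) {
        imp[tab$Feature] <- tab$Gain
      }
      imp
    },
    stop_dc("kernel `%s` has no importance measure (RFE kernels are %s)",
            model$name, paste(KERNEL_LEVELS, collapse = ", "),
            class = "dynconn_value_error"))
  imp <- imp[model$feature_names]
  imp[!is.finite(imp)] <- 0
  names(imp) <- model$feature_names
  imp
}

# ---- cross-validation utilities -----------------------------------------

# Stratified k-fold assignment: within each class, a seeded permutation is
# dealt round-robin into folds, so class balance is preserved per fold.
stratified_folds <- function(y, k, seed) {
  y <- as_binary_factor(y)
  if (min(table(y)) < k) {
    stop_dc("smallest class has %d samples, fewer than %d folds",
            min(table(y)), k, class = "dynconn_value_error")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

balanced_accuracy_score <- function(truth, pred, positive = POSITIVE_CLASS) {
  truth <- as.character(truth); pred <- as.character(pred)
  pos <- truth == positive
  sens <- mean(pred[pos] == positive)
  spec <- mean(pred[!pos] != positive)
  (sens + spec) / 2
}

# Mean CV balanced accuracy of `name` with `params` over precomputed folds.
# Scale-sensitive kernels are standardised with train-fold statistics.
# `cols_by_fold` optionally restricts each fold to its own feature subset
# (nested selection).
cv_balanced_accuracy <- function(name, X, y, fold, params = NULL, seed = 1,
                                 per_fold = FALSE, cols_by_fold = NULL) {
  y <- as_binary_factor(y)
  k <- max(fold)
  pos <- positive_level(y)
  scores <- matrix(NA_real_, k, 4L,
                   dimnames = list(NULL, c("accuracy", "sensitivity",
                                           "specificity", "balanced_accuracy")))
  for (f in seq_len(k)) {
    tr <- fold != f
    cols <- if (is.null(cols_by_fold)) seq_len(ncol(X)) else cols_by_fold[[f]]
    Xtr <- X[tr, cols, drop = FALSE]; Xte <- X[!tr, cols, drop = FALSE]
    if (needs_scaling(name)) {
      sp <- scale_params(Xtr)
      Xtr <- apply_scale(Xtr, sp); Xte <- apply_scale(Xte, sp)
    }
    model <- fit_kernel(name, Xtr, y[tr], params,
                        seed = derive_seed(seed, paste0("fold/", f)))
    pred <- predict_kernel(model, Xte)
    truth <- y[!tr]
    tp <- sum(truth == pos & pred == pos)
    tn <- sum(truth != pos & pred != pos)
    fp <- sum(truth != pos & pred == pos)
    fn <- sum(truth == pos & pred != pos)
    m <- confusion_metrics(tp, tn, fp, fn)
    scores[f, ] <- c(m$accuracy, m$sensitivity, m$specificity,
                     m$balanced_accuracy)
  }
  if (per_fold) scores else mean(scores[, "balanced_accuracy"])
}
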