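# Shared fixtures and independent oracles, built in code at test time.

# Naive slice-taper-correlate loop: the independent oracle for
# windowed_correlations().  Slices each window, optionally mean-centres,
# tapers with the Gaussian, and calls pearson() on the tapered segments.
naive_windowed <- function(x, y, win = gaussian_window_spec(), center = TRUE) {
  w <- win$width_tr
  g <- exp(-((seq_len(w) - 1 - (w - 1) / 2)^2) / (2 * win$sigma_tr^2))
  starts <- seq(1L, length(x) - w + 1L, by = win$step_tr)
  vapply(starts, function(s) {
    xs <- x[s:(s + w - 1L)]
    ys <- y[s:(s + w - 1L)]
    if (center) {
      xs <- xs - mean(xs)
      ys <- ys - mean(ys)
    }
    as.numeric(pearson(xs * g, ys * g))
  }, numeric(1))
}

# One subject with a single state-switching pair, for estimator checks.
switching_pair <- function(fraction, length_tr = 2000, base_corr = 0.95,
                           seed = 1) {
  m <- state_model(2, base_corr = base_corr,
                   pairs = data.frame(i = 1, j = 2, fraction = fraction))
  ts <- simulate_subject(m, length_tr, seed = seed)
  list(x = ts$data[, 1], y = ts$data[, 2])
}

# Balanced full configuration grid (2 x 2 x 4 x 4 x 6) with N(mu, sd) scores;
# optional per-level mean shifts named by factor, e.g. shift = c(dFC = 0.05).
make_grid_table <- function(seed = 1, mu = 0.7, sd = 0.03, shift = NULL,
                            reps = 1) {
  grid <- expand.grid(
    representation = c("FC", "dFC"), atlas = c("AAL", "TT"),
    strategy = c("filt_global", "filt_noglobal", "nofilt_global",
                 "nofilt_noglobal"),
    kernel = c("lsvm", "lr", "rf", "lgbm"),
    classifier = c("lsvm", "lr", "rf", "lgbm", "nn", "svm"),
    stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), reps), , drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "out.attrs") <- NULL
  set.seed(seed)
  grid$score <- mu + rnorm(nrow(grid), 0, sd)
  if (!is.null(shift)) {
    for (lev in names(shift)) {
      hit <- Reduce(`|`, lapply(grid[1:5], function(col) col == lev))
      grid$score <- grid$score + ifelse(hit, shift[[lev]], 0)
    }
  }
  grid$score_sd <- sd
  grid
}

# Classical one-way two-group ANOVA F by the direct textbook formula:
# the closed-form oracle for the single-factor ANOVA reduction.
oneway_f_oracle <- function(score, group) {
  groups <- split(score, group)
  n <- lengths(groups)
  gm <- mean(score)
  ss_between <- sum(n * (vapply(groups, mean, numeric(1)) - gm)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(score) - length(groups)
  (ss_between / df1) / (ss_within / df2)
}

# Independent CV balanced accuracy of a linear SVM on a feature subset:
# train-fold standardisation, e1071 fit, balanced accuracy on the test
# fold.  Used to score subsets for the exhaustive-RFE comparison.
lsvm_cv_oracle <- function(X, y, cols, fold) {
  k <- max(fold)
  bal <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    Xtr <- X[tr, cols, drop = FALSE]
    Xte <- X[!tr, cols, drop = FALSE]
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(fit, Xte)
    truth <- y[!tr]
    sens <- mean(pred[truth == "ASD"] == "ASD")
    spec <- mean(pred[truth == "TD"] == "TD")
    bal[f] <- (sens + spec) / 2
  }
  mean(bal)
}

# Small two-group labelled matrix with `n_signal` mean-shifted features.
planted_matrix <- function(n_per_group = 50, n_signal = 5, n_noise = 200,
                           delta = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  X <- matrix(rnorm(n * (n_signal + n_noise)), n)
  colnames(X) <- c(sprintf("sig%02d", seq_len(n_signal)),
                   sprintf("noise%03d", seq_len(n_noise)))
  asd <- seq_len(n_per_group)
  X[asd, seq_len(n_signal)] <- X[asd, seq_len(n_signal)] + delta
  y <- factor(rep(c("ASD", "TD"), each = n_per_group), levels = c("TD", "ASD"))
  list(X = X, y = y)
}
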