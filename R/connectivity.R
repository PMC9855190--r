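# Feature representations: static FC (full-series Pearson per region pair)
# and dynamic dFC (per-pair fractions of Gaussian-tapered sliding-window
# correlations that are strong / weak).

#' Gaussian sliding-window specification
#'
#' The window slides in steps of `step_tr` over the series; each windowed
#' segment is tapered by a Gaussian `g(t) = exp(-(t - c)^2 / (2 sigma^2))`
#' centred at the window midpoint `c = (w - 1) / 2`.  The defaults
#' (w = 21 TR, sigma = 3 TR, step 1 TR) follow common sliding-window
#' dynamic-connectivity practice.
#'
#' @param width_tr Window width w in TR (>= 2).
#' @param sigma_tr Taper standard deviation in TR (> 0).
#' @param step_tr Step size s in TR (>= 1).
#' @return Object of class `gaussian_window_spec`.
#' @export
gaussian_window_spec <- function(width_tr = 21, sigma_tr = 3, step_tr = 1) {
  assert_scalar_number(width_tr, "width_tr", lower = 2)
  assert_scalar_number(sigma_tr, "sigma_tr", lower = 1e-12)
  assert_scalar_number(step_tr, "step_tr", lower = 1)
  structure(list(width_tr = as.integer(width_tr), sigma_tr = sigma_tr,
                 step_tr = as.integer(step_tr)),
            class = "gaussian_window_spec")
}

#' Strong/weak correlation thresholds for dynamic connectivity
#'
#' A windowed correlation rho counts as "strong" when `rho >= strong_min`
#' (default 0.8) and as "weak/no correlation" when `rho <= weak_max`
#' (default 0.25).  The weak criterion is applied to the signed rho by
#' default; set `abs_weak = TRUE` to use `|rho| <= weak_max` instead.
#'
#' @param strong_min Strong threshold, in (weak_max, 1].
#' @param weak_max Weak threshold, in [-1, strong_min).
#' @param abs_weak Apply the weak criterion to `|rho|`?
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(strong_min = 0.8, weak_max = 0.25, abs_weak = FALSE) {
  assert_scalar_number(strong_min, "strong_min", lower = -1, upper = 1)
  assert_scalar_number(weak_max, "weak_max", lower = -1, upper = 1)
  if (weak_max >= strong_min) {
    stop_dc("weak_max (%g) must be below strong_min (%g)", weak_max, strong_min,
            class = "dynconn_value_error")
  }
  structure(list(strong_min = strong_min, weak_max = weak_max,
                 abs_weak = isTRUE(abs_weak)),
            class = "threshold_spec")
}

#' Sample Pearson correlation
#'
#' Standard sample Pearson correlation of two equal-length series.  If
#' either series has zero variance the correlation is undefined; 0 is
#' returned with attribute `degenerate = TRUE` (a flat signal is treated
#' as maximally unconnected downstream).
#'
#' @param x,y Numeric vectors of equal length >= 2 with finite values.
#' @return Correlation in `[-1, 1]`, possibly with attribute `degenerate`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop_dc("series lengths differ (%d vs %d)", length(x), length(y),
            class = "dynconn_value_error")
  }
  if (length(x) < 2L) {
    stop_dc("need at least 2 observations", class = "dynconn_value_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_dc("non-finite values in input series", class = "dynconn_value_error")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) {
    return(structure(0, degenerate = TRUE))
  }
  r <- sum(xc * yc) / den
  min(1, max(-1, r))
}

# Names of the upper-triangle pairs (i < j, row-major order).
pair_names <- function(labels) {
  A <- length(labels)
  idx <- which(upper.tri(matrix(0, A, A)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  list(i = idx[, 1L], j = idx[, 2L],
       name = paste0(labels[idx[, 1L]], "__", labels[idx[, 2L]]))
}

#' Static functional connectivity feature vector
#'
#' Pairwise full-series Pearson correlations over the upper triangle
#' (i < j, row-major), i.e. `A (A - 1) / 2` features for A regions, named
#' `Ri__Rj` from the region labels.
#'
#' @param ts A [roi_time_series()].
#' @return Named numeric vector of length `A (A - 1) / 2`.
#' @export
static_fc <- function(ts) {
  stopifnot(inherits(ts, "roi_time_series"))
  pn <- pair_names(ts$region_labels)
  cm <- suppressWarnings(cor(ts$data))
  v <- cm[cbind(pn$i, pn$j)]
  v[!is.finite(v)] <- 0  # zero-variance region: degenerate, count as unconnected
  names(v) <- pn$name
  v
}

#' Number of sliding-window positions
#'
#' Counts the fully contained window placements:
#' `M = floor((L - w) / s) + 1`.
#'
#' @param length_tr Series length L.
#' @param win A [gaussian_window_spec()].
#' @return Integer M >= 1.
#' @export
num_windows <- function(length_tr, win = gaussian_window_spec()) {
  stopifnot(inherits(win, "gaussian_window_spec"))
  if (length_tr < win$width_tr) {
    stop_dc("series length %d shorter than window width %d", length_tr,
            win$width_tr, class = "dynconn_length_error")
  }
  as.integer((length_tr - win$width_tr) %/% win$step_tr + 1L)
}

gaussian_taper <- function(win) {
  t <- seq_len(win$width_tr) - 1
  c0 <- (win$width_tr - 1) / 2
  exp(-((t - c0)^2) / (2 * win$sigma_tr^2))
}

#' Sliding-window tapered correlations of one region pair
#'
#' For each of the M window positions, both segments are mean-centred
#' within the window, multiplied pointwise by the Gaussian taper, and the
#' Pearson correlation of the two tapered segments is computed.
#' Zero-variance windows yield 0 (degenerate, counted as weak downstream).
#' Set `center = FALSE` for the literal taper-without-centring variant.
#'
#' @param x,y Numeric series of equal length `>= width_tr`.
#' @param win A [gaussian_window_spec()].
#' @param center Mean-centre each windowed segment before tapering?
#' @return Numeric vector of the M windowed correlations.
#' @export
windowed_correlations <- function(x, y, win = gaussian_window_spec(),
                                  center = TRUE) {
  if (length(x) != length(y)) {
    stop_dc("series lengths differ (%d vs %d)", length(x), length(y),
            class = "dynconn_value_error")
  }
  M <- num_windows(length(x), win)
  w <- win$width_tr
  starts <- seq(0L, by = win$step_tr, length.out = M)
  idx <- outer(starts, seq_len(w), `+`)
  g <- gaussian_taper(win)
  X <- matrix(x[idx], M, w)
  Y <- matrix(y[idx], M, w)
  if (center) {
    X <- X - rowMeans(X)
    Y <- Y - rowMeans(Y)
  }
  X <- X * rep(g, each = M)
  Y <- Y * rep(g, each = M)
  # Pearson of the tapered segments (re-centred by their own means)
  X <- X - rowMeans(X)
  Y <- Y - rowMeans(Y)
  num <- rowSums(X * Y)
  den2 <- rowSums(X^2) * rowSums(Y^2)
  r <- numeric(M)
  ok <- den2 > 0
  r[ok] <- num[ok] / sqrt(den2[ok])
  pmin(1, pmax(-1, r))
}

#' Strong/weak window fractions for one pair
#'
#' Reduces a series of M windowed correlations to the dynamic-connectivity
#' summary: `nst`, the fraction of windows with `rho >= strong_min`
#' (over-connectivity), and `nwk`, the fraction with `rho <= weak_max`
#' (under-/no connectivity).
#'
#' @param rhos Numeric vector of windowed correlations (M >= 1).
#' @param thr A [threshold_spec()].
#' @return Named numeric vector `c(nwk = ..., nst = ...)`, both in
#'   `[0, 1]`.
#' @export
dfc_pair <- function(rhos, thr = threshold_spec()) {
  stopifnot(inherits(thr, "threshold_spec"))
  if (length(rhos) < 1L) {
    stop_dc("empty windowed-correlation series", class = "dynconn_value_error")
  }
  wk_val <- if (thr$abs_weak) abs(rhos) else rhos
  c(nwk = mean(wk_val <= thr$weak_max), nst = mean(rhos >= thr$strong_min))
}

#' Dynamic functional connectivity feature vector
#'
#' For each region pair (i < j, row-major) computes the windowed
#' correlations and their strong/weak fractions, yielding `A (A - 1)`
#' features named `Ri__Rj_wk` and `Ri__Rj_st` (weak before strong) — twice
#' the static FC length.
#'
#' @param ts A [roi_time_series()].
#' @param win A [gaussian_window_spec()].
#' @param thr A [threshold_spec()].
#' @param center Passed to [windowed_correlations()].
#' @return Named numeric vector of length `A (A - 1)`, values in `[0, 1]`.
#' @export
dfc_features <- function(ts, win = gaussian_window_spec(),
                         thr = threshold_spec(), center = TRUE) {
  stopifnot(inherits(ts, "roi_time_series"))
  if (nrow(ts$data) < win$width_tr) {
    stop_dc("subject %s: series length %d shorter than window width %d",
            ts$subject_id, nrow(ts$data), win$width_tr,
            class = "dynconn_length_error")
  }
  pn <- pair_names(ts$region_labels)
  n_pairs <- length(pn$name)
  out <- numeric(2L * n_pairs)
  nms <- character(2L * n_pairs)
  for (k in seq_len(n_pairs)) {
    rhos <- windowed_correlations(ts$data[, pn$i[k]], ts$data[, pn$j[k]],
                                  win, center = center)
    f <- dfc_pair(rhos, thr)
    out[2L * k - 1L] <- f[["nwk"]]
    out[2L * k] <- f[["nst"]]
    nms[2L * k - 1L] <- paste0(pn$name[k], "_wk")
    nms[2L * k] <- paste0(pn$name[k], "_st")
  }
  names(out) <- nms
  out
}

#' Assemble the subjects-by-features matrix for a cohort
#'
#' One row per subject in cohort order; columns are the canonical feature
#' names of the chosen representation (`FC`: `A(A-1)/2` correlations in
#' `[-1, 1]`; `dFC`: `A(A-1)` window fractions in `[0, 1]`).
#'
#' @param cohort A [cohort()].
#' @param representation `"FC"` or `"dFC"`.
#' @param win,thr Window and threshold specs (dFC only).
#' @param center Passed to [windowed_correlations()] (dFC only).
#' @return Object of class `feature_matrix`: list with `values` (matrix
#'   with subject row names and feature column names), `feature_names`,
#'   `representation`, `atlas_tag`, `strategy_tag`, `subject_ids`.
#' @export
build_feature_matrix <- function(cohort, representation = c("FC", "dFC"),
                                 win = gaussian_window_spec(),
                                 thr = threshold_spec(), center = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  representation <- match.arg(representation)
  rows <- lapply(cohort$subjects, function(s) {
    tryCatch(
      if (representation == "FC") static_fc(s)
      else dfc_features(s, win, thr, center = center),
      error = function(e) {
        stop_dc("feature extraction failed for subject %s: %s", s$subject_id,
                conditionMessage(e), class = "dynconn_subject_error")
      })
  })
  values <- do.call(rbind, rows)
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  rownames(values) <- ids
  structure(
    list(values = values, feature_names = colnames(values),
         representation = representation,
         atlas_tag = cohort$subjects[[1L]]$atlas_tag,
         strategy_tag = cohort$subjects[[1L]]$strategy_tag,
         subject_ids = ids),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d subjects x %d features (%s/%s)\n",
              x$representation, nrow(x$values), ncol(x$values),
              x$atlas_tag, x$strategy_tag))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Subjects in rows (first column `subject_id`), named features in columns.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @param representation,atlas_tag,strategy_tag Metadata restored on read.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` the `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(subject_id = fm$subject_ids, fm$values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, representation, atlas_tag = "AAL",
                                strategy_tag = "filt_global") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df$subject_id
  structure(
    list(values = values, feature_names = colnames(values),
         representation = match.arg(representation, REPRESENTATION_LEVELS),
         atlas_tag = match.arg(atlas_tag, ATLAS_LEVELS),
         strategy_tag = match.arg(strategy_tag, STRATEGY_LEVELS),
         subject_ids = df$subject_id),
    class = "feature_matrix")
}
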