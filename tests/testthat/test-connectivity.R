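test_that("pearson matches hand-computed and degenerate cases", {
  x <- c(1, 5, 2, 8)
  expect_equal(as.numeric(pearson(x, x)), 1.0)
  expect_equal(as.numeric(pearson(c(1, 2, 3), c(3, 2, 1))), -1.0)
  # closed form: cov = 3/2, sx = 1, sy^2 = 7/3 (sample), rho = 0.98198...
  expect_equal(as.numeric(pearson(c(1, 2, 3), c(1, 2, 4))), 0.98198,
               tolerance = 1e-5)
  expect_identical(as.numeric(pearson(x, x)), as.numeric(pearson(x, x)))
  expect_error(pearson(1:3, 1:4), class = "dynconn_value_error")
  flat <- pearson(c(2, 2, 2), c(1, 2, 3))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
})

test_that("pearson is symmetric on random series", {
  set.seed(10)
  for (k in 1:10) {
    x <- rnorm(30)
    y <- rnorm(30)
    expect_equal(as.numeric(pearson(x, y)), as.numeric(pearson(y, x)))
  }
})

test_that("static FC has the atlas-determined length and canonical names", {
  for (A in c(116L, 97L)) {
    labs <- sprintf("Reg%03d", seq_len(A))
    ts <- roi_time_series("s", matrix(rnorm(10 * A), 10), 2, labs)
    v <- static_fc(ts)
    expect_identical(length(v), as.integer(A * (A - 1) / 2))
    expect_identical(names(v)[1], paste0(labs[1], "__", labs[2]))
  }
  m <- matrix(rnorm(20), 10, 2)
  m[, 2] <- m[, 1]
  ts2 <- roi_time_series("s", m, 2, c("a", "b"))
  expect_equal(unname(static_fc(ts2)), 1.0)
})

test_that("window count follows the fully-contained convention", {
  w <- gaussian_window_spec()
  expect_identical(num_windows(21, w), 1L)
  expect_identical(num_windows(200, w), 180L)  # start offsets 0..179
  expect_error(num_windows(20, w), class = "dynconn_length_error")
  expect_identical(num_windows(30, gaussian_window_spec(10, 3, 4)), 6L)
})

test_that("windowed correlations preserve exact (anti-)correlation", {
  set.seed(3)
  x <- rnorm(120)
  expect_equal(windowed_correlations(x, x), rep(1, 100), tolerance = 1e-12)
  expect_equal(windowed_correlations(x, -x), rep(-1, 100), tolerance = 1e-12)
})

test_that("windowed correlations match the naive slice-taper-correlate loop", {
  set.seed(8)
  for (k in 1:10) {
    x <- rnorm(80)
    y <- rnorm(80)
    win <- gaussian_window_spec(sample(5:25, 1), runif(1, 1, 5),
                                sample(1:3, 1))
    expect_equal(windowed_correlations(x, y, win), naive_windowed(x, y, win),
                 tolerance = 1e-10)
    expect_equal(windowed_correlations(x, y, win, center = FALSE),
                 naive_windowed(x, y, win, center = FALSE), tolerance = 1e-10)
  }
})

test_that("a planted half-connected pair yields nst near one half", {
  p <- switching_pair(0.5, length_tr = 2000, seed = 101)
  rhos <- windowed_correlations(p$x, p$y)
  expect_lt(abs(mean(rhos >= 0.8) - 0.5), 0.07)
})

test_that("strong/weak window fractions count correctly", {
  expect_equal(dfc_pair(c(0.9, 0.1, 0.3, 0.85)),
               c(nwk = 0.25, nst = 0.5))
  expect_equal(dfc_pair(rep(0.9, 5)), c(nwk = 0, nst = 1))
  expect_equal(dfc_pair(rep(0.5, 5)), c(nwk = 0, nst = 0))
  expect_error(dfc_pair(numeric(0)), class = "dynconn_value_error")
  # signed weak criterion by default; magnitude variant on request
  expect_equal(dfc_pair(c(-0.9, 0.9))[["nwk"]], 0.5)
  expect_equal(dfc_pair(c(-0.9, 0.9), threshold_spec(abs_weak = TRUE))[["nwk"]], 0)
})

test_that("threshold monotonicity: stricter strong never raises nst, looser weak never lowers nwk", {
  set.seed(12)
  rhos <- runif(200, -1, 1)
  strong_grid <- seq(0.5, 0.95, by = 0.05)
  nst <- vapply(strong_grid,
                function(s) dfc_pair(rhos, threshold_spec(s, 0.25))[["nst"]],
                numeric(1))
  expect_true(all(diff(nst) <= 0))
  weak_grid <- seq(-0.5, 0.45, by = 0.05)
  nwk <- vapply(weak_grid,
                function(wk) dfc_pair(rhos, threshold_spec(0.8, wk))[["nwk"]],
                numeric(1))
  expect_true(all(diff(nwk) >= 0))
})

test_that("dFC feature vectors double static length with wk/st naming", {
  labs97 <- sprintf("Reg%03d", 1:97)
  ts <- roi_time_series("s", matrix(rnorm(25 * 97), 25), 2, labs97)
  v <- dfc_features(ts)
  expect_identical(length(v), 2L * 4656L)  # 9312

  m <- matrix(rnorm(25 * 2), 25)
  ts2 <- roi_time_series("s", m, 2, c("Precentral_L", "Rolandic_Oper_R"))
  v2 <- dfc_features(ts2)
  expect_identical(names(v2),
                   c("Precentral_L__Rolandic_Oper_R_wk",
                     "Precentral_L__Rolandic_Oper_R_st"))

  short <- roi_time_series("tiny", matrix(rnorm(10 * 2), 10), 2, c("a", "b"))
  expect_error(dfc_features(short), "tiny", class = "dynconn_length_error")
})

test_that("feature matrices assemble per cohort with representation invariants", {
  coh <- simulate_cohort(3, 2, state_model(10, 0.9), length_tr = 60, seed = 2)
  fc <- build_feature_matrix(coh, "FC")
  expect_identical(dim(fc$values), c(5L, 45L))
  expect_true(all(fc$values >= -1 & fc$values <= 1))

  dfc <- build_feature_matrix(coh, "dFC")
  expect_identical(dim(dfc$values), c(5L, 90L))
  expect_true(all(dfc$values >= 0 & dfc$values <= 1))
  expect_true(all(grepl("_(wk|st)$", dfc$feature_names)))
  expect_identical(rownames(dfc$values), coh$phenotypes$subject_id)

  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(dfc, f)
  back <- read_feature_matrix(f, "dFC")
  expect_equal(back$values, dfc$values, tolerance = 1e-12)
})
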