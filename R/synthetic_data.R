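# Synthetic cohorts: multi-region BOLD-like series with a known
# state-switching correlation structure and plantable group differences.

#' Specify a state-switching connectivity model
#'
#' Each targeted region pair alternates between a "connected" state, in
#' which the two regions are drawn as bivariate Gaussians at correlation
#' `base_corr`, and a "disconnected" state of independent draws.  All other
#' region pairs are independent unit-variance Gaussian noise (correlation
#' ~ 0), so arbitrary per-pair connected fractions are always jointly
#' feasible.  A region may participate in at most one targeted pair.
#'
#' Two state-sequence designs are available.  The default, `"blocks"`,
#' tiles time with fixed cycles of length `period_tr` containing
#' `round(fraction * period_tr)` connected TRs each (random phase per
#' subject/pair): the realized connected fraction is then exact for every
#' full cycle, which is what makes the window-count statistics consistent
#' estimators of the planted fraction.  `"geometric"` draws alternating
#' geometric dwell times with mean `segment_length_tr` in the connected
#' state, a rougher but less regular alternative whose realized fraction
#' fluctuates substantially at typical scan lengths.
#'
#' @param n_regions Number of atlas regions A (>= 2).
#' @param base_corr Correlation while connected, |base_corr| < 1.
#' @param pairs `data.frame` with integer columns `i`, `j` (1-based region
#'   indices, i != j) and numeric `fraction` in `[0, 1]` (target fraction of
#'   time connected).  Optionally a `corr` column overriding `base_corr`
#'   per pair.  `NULL` for a fully unstructured model.
#' @param segment_mode `"blocks"` (default) or `"geometric"`; see Details.
#' @param period_tr Cycle length in TR for `"blocks"` mode.
#' @param segment_length_tr Mean connected dwell in TR for `"geometric"`
#'   mode.
#' @return Object of class `state_model`.
#' @export
state_model <- function(n_regions, base_corr = 0.9, pairs = NULL,
                        segment_mode = c("blocks", "geometric"),
                        period_tr = 200, segment_length_tr = 30) {
  stopifnot(n_regions >= 2)
  assert_scalar_number(base_corr, "base_corr", lower = -1, upper = 1)
  if (abs(base_corr) >= 1) {
    stop_dc("|base_corr| must be < 1", class = "dynconn_model_error")
  }
  segment_mode <- match.arg(segment_mode)
  assert_scalar_number(period_tr, "period_tr", lower = 2)
  assert_scalar_number(segment_length_tr, "segment_length_tr", lower = 1)
  if (!is.null(pairs)) {
    stopifnot(is.data.frame(pairs), all(c("i", "j", "fraction") %in% names(pairs)))
    if (any(pairs$i == pairs$j) ||
        any(pairs$i < 1 | pairs$i > n_regions | pairs$j < 1 | pairs$j > n_regions)) {
      stop_dc("pair indices must be distinct regions in 1..%d", n_regions,
              class = "dynconn_model_error")
    }
    if (any(pairs$fraction < 0 | pairs$fraction > 1)) {
      stop_dc("pair state fractions must lie in [0, 1]", class = "dynconn_model_error")
    }
    touched <- c(pairs$i, pairs$j)
    if (anyDuplicated(touched)) {
      stop_dc("region(s) %s appear in more than one targeted pair; joint correlation structure would be infeasible",
              paste(unique(touched[duplicated(touched)]), collapse = ", "),
              class = "dynconn_model_error")
    }
    if ("corr" %in% names(pairs) && any(abs(pairs$corr) >= 1)) {
      stop_dc("per-pair |corr| must be < 1", class = "dynconn_model_error")
    }
  }
  structure(list(n_regions = as.integer(n_regions), base_corr = base_corr,
                 pairs = pairs, segment_mode = segment_mode,
                 period_tr = as.integer(period_tr),
                 segment_length_tr = segment_length_tr),
            class = "state_model")
}

#' Specify a planted group difference in connectivity dynamics
#'
#' For the affected pairs, ASD subjects use `fraction_asd` (and optionally
#' connected-state correlation `corr_asd`) while TD subjects use
#' `fraction_td` / `corr_td`.  Choosing the two groups so that
#' `fraction * corr` matches plants a purely *dynamic* difference: equal
#' full-series correlation (invisible to static FC) but different
#' window-fraction signatures.
#'
#' @param affected_pairs `data.frame` with columns `i`, `j` (region
#'   indices).
#' @param fraction_asd,fraction_td Connected-state fractions in `[0, 1]`.
#' @param corr_asd,corr_td Optional connected-state correlations
#'   (default: the model's `base_corr`).
#' @return Object of class `group_effect`.
#' @export
group_effect <- function(affected_pairs, fraction_asd, fraction_td,
                         corr_asd = NULL, corr_td = NULL) {
  stopifnot(is.data.frame(affected_pairs), all(c("i", "j") %in% names(affected_pairs)))
  assert_scalar_number(fraction_asd, "fraction_asd", lower = 0, upper = 1)
  assert_scalar_number(fraction_td, "fraction_td", lower = 0, upper = 1)
  if (!is.null(corr_asd)) assert_scalar_number(corr_asd, "corr_asd", -1, 1)
  if (!is.null(corr_td)) assert_scalar_number(corr_td, "corr_td", -1, 1)
  structure(list(affected_pairs = affected_pairs, fraction_asd = fraction_asd,
                 fraction_td = fraction_td, corr_asd = corr_asd,
                 corr_td = corr_td),
            class = "group_effect")
}

# Connected/disconnected indicator sequence of length L for one pair.
state_sequence <- function(model, fraction, length_tr) {
  if (fraction <= 0) return(rep(FALSE, length_tr))
  if (fraction >= 1) return(rep(TRUE, length_tr))
  if (model$segment_mode == "blocks") {
    p <- model$period_tr
    n_on <- round(fraction * p)
    if (n_on == 0L) return(rep(FALSE, length_tr))
    if (n_on == p) return(rep(TRUE, length_tr))
    cyc <- c(rep(TRUE, n_on), rep(FALSE, p - n_on))
    phase <- sample.int(p, 1L) - 1L
    rep(cyc, length.out = length_tr + phase)[(phase + 1L):(phase + length_tr)]
  } else {
    dwell_on <- model$segment_length_tr
    dwell_off <- dwell_on * (1 - fraction) / fraction
    s <- logical(0)
    on <- runif(1) < fraction
    while (length(s) < length_tr) {
      d <- rgeom(1L, 1 / (if (on) dwell_on else dwell_off)) + 1L
      s <- c(s, rep(on, d))
      on <- !on
    }
    s[seq_len(length_tr)]
  }
}

#' Simulate one subject's ROI time series
#'
#' All regions start as independent standard-normal noise; each targeted
#' pair's second region is rebuilt, during connected segments, as a
#' correlated draw against the first region (correlation `corr`), keeping
#' unit marginal variance throughout.  Deterministic given `seed`.
#'
#' @param model A [state_model()].
#' @param length_tr Number of volumes T.
#' @param tr_seconds Repetition time in seconds.
#' @param seed Integer seed.
#' @param subject_id,strategy_tag,atlas_tag Metadata for the returned
#'   series.
#' @return A [roi_time_series()].
#' @export
simulate_subject <- function(model, length_tr, tr_seconds = 2, seed = 1,
                             subject_id = sprintf("sim_%06d", seed %% 1000000L),
                             strategy_tag = "filt_global", atlas_tag = "AAL") {
  stopifnot(inherits(model, "state_model"))
  assert_scalar_number(length_tr, "length_tr", lower = 2)
  with_seed(seed, {
    A <- model$n_regions
    x <- matrix(rnorm(length_tr * A), nrow = length_tr, ncol = A)
    if (!is.null(model$pairs)) {
      for (k in seq_len(nrow(model$pairs))) {
        pr <- model$pairs[k, ]
        rho <- if ("corr" %in% names(pr) && !is.na(pr$corr)) pr$corr else model$base_corr
        st <- state_sequence(model, pr$fraction, length_tr)
        e <- rnorm(length_tr)
        x[, pr$j] <- ifelse(st, rho * x[, pr$i] + sqrt(1 - rho^2) * e, e)
      }
    }
    roi_time_series(subject_id, x, tr_seconds,
                    region_labels = sprintf("R%03d", seq_len(A)),
                    strategy_tag = strategy_tag, atlas_tag = atlas_tag)
  })
}

# Demographics loosely shaped like a multi-site autism cohort: age normal
# (17, 8) truncated at 6 years, sex ~84% male, FIQ normal (108, 15).
simulate_phenotype_row <- function(subject_id, dx, seed) {
  with_seed(seed, {
    age <- 0
    while (age < 6) age <- rnorm(1, 17, 8)
    data.frame(subject_id = subject_id, dx = dx, site = "SYNTH",
               age_years = round(age, 1),
               sex = if (rbinom(1, 1, 0.84) == 1) "M" else "F",
               fiq = round(rnorm(1, 108, 15), 1),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a two-group cohort with a planted connectivity difference
#'
#' Generates `n_asd` + `n_td` subjects from `model`, applying the group
#' effect's fractions (and optional correlations) to the affected pairs.
#' Per-subject seeds are derived deterministically from `seed`, so the
#' whole cohort is a pure function of its arguments.
#'
#' @param n_asd,n_td Group sizes (>= 1).
#' @param model A [state_model()].
#' @param effect A [group_effect()], or `NULL` for no group difference.
#' @param length_tr Volumes per subject.
#' @param tr_seconds Repetition time in seconds.
#' @param seed Master integer seed.
#' @param strategy_tag,atlas_tag Metadata tags.
#' @return A [cohort()].
#' @export
simulate_cohort <- function(n_asd, n_td, model, effect = NULL, length_tr = 200,
                            tr_seconds = 2, seed = 1,
                            strategy_tag = "filt_global", atlas_tag = "AAL") {
  if (n_asd < 1 || n_td < 1) {
    stop_dc("both groups need at least one subject (got n_asd=%d, n_td=%d)",
            n_asd, n_td, class = "dynconn_value_error")
  }
  stopifnot(inherits(model, "state_model"))
  if (!is.null(effect)) stopifnot(inherits(effect, "group_effect"))

  group_model <- function(dx) {
    if (is.null(effect)) return(model)
    frac <- if (dx == "ASD") effect$fraction_asd else effect$fraction_td
    corr <- if (dx == "ASD") effect$corr_asd else effect$corr_td
    add <- effect$affected_pairs
    add$fraction <- frac
    add$corr <- corr %||% model$base_corr
    base <- model$pairs
    if (!is.null(base)) {
      if (!("corr" %in% names(base))) base$corr <- model$base_corr
      keep <- !(paste(base$i, base$j) %in% paste(add$i, add$j))
      add <- rbind(base[keep, c("i", "j", "fraction", "corr")], add)
    }
    m <- model
    m$pairs <- NULL
    m <- state_model(model$n_regions, model$base_corr, add,
                     segment_mode = model$segment_mode,
                     period_tr = model$period_tr,
                     segment_length_tr = model$segment_length_tr)
    m
  }

  dxs <- c(rep("ASD", n_asd), rep("TD", n_td))
  ids <- sprintf("sim_%s_%03d", tolower(dxs),
                 c(seq_len(n_asd), seq_len(n_td)))
  subjects <- vector("list", length(ids))
  phen <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sk <- derive_seed(seed, paste0("subject/", ids[k]))
    subjects[[k]] <- simulate_subject(group_model(dxs[k]), length_tr, tr_seconds,
                                      seed = sk, subject_id = ids[k],
                                      strategy_tag = strategy_tag,
                                      atlas_tag = atlas_tag)
    phen[[k]] <- simulate_phenotype_row(ids[k], dxs[k],
                                        derive_seed(seed, paste0("phen/", ids[k])))
  }
  phenotypes <- do.call(rbind, phen)
  class(phenotypes) <- c("phenotype_table", "data.frame")
  cohort(subjects, phenotypes)
}
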