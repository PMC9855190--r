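# Factorial analysis of pipeline-configuration effects: three-factor
# type-III ANOVA with interaction pruning, factor-level summaries, and
# selected-feature region reports.

anova_table_from_car <- function(fit, car_tab) {
  keep <- !(rownames(car_tab) %in% c("(Intercept)"))
  tab <- car_tab[keep, , drop = FALSE]
  resid_row <- rownames(tab) == "Residuals"
  terms_df <- data.frame(
    term = rownames(tab)[!resid_row],
    sum_sq = tab[!resid_row, "Sum Sq"],
    df = tab[!resid_row, "Df"],
    F = tab[!resid_row, "F value"],
    p = tab[!resid_row, "Pr(>F)"],
    stringsAsFactors = FALSE)
  rownames(terms_df) <- NULL
  structure(list(terms = terms_df,
                 residual = list(sum_sq = tab[resid_row, "Sum Sq"],
                                 df = tab[resid_row, "Df"]),
                 ss_type = "III", fit = fit),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  cat(sprintf("<anova_table> type %s sums of squares\n", x$ss_type))
  print(cbind(x$terms[1L],
              signif(x$terms[-1L], digits)), row.names = FALSE)
  cat(sprintf("Residuals: sum_sq %.4g on %d df\n", x$residual$sum_sq,
              x$residual$df))
  invisible(x)
}

fit_type3 <- function(table, formula) {
  dat <- table
  for (f in all.vars(formula)[-1L]) {
    dat[[f]] <- factor(dat[[f]])
  }
  ctr <- lapply(all.vars(formula)[-1L], function(f) "contr.sum")
  names(ctr) <- all.vars(formula)[-1L]
  fit <- lm(formula, data = dat, contrasts = ctr)
  if (any(is.na(coef(fit)))) {
    # identify empty design cells for the error message
    fac <- all.vars(formula)[-1L]
    cells <- table(do.call(interaction, c(dat[fac], drop = FALSE)))
    empty <- names(cells)[cells == 0]
    stop_dc("rank-deficient design%s",
            if (length(empty) > 0L)
              paste0("; empty cell(s): ", paste(empty, collapse = ", "))
            else "",
            class = "dynconn_design_error")
  }
  anova_table_from_car(fit, car::Anova(fit, type = 3))
}

#' Three-factor type-III ANOVA of the configuration grid
#'
#' Fits `score ~ feat * strat * atls` (all main effects and interactions)
#' on the long-format configuration results table, with sum-to-zero factor
#' coding and type-III sums of squares, then refits keeping all main
#' effects but only the interactions whose full-fit p-value is at most
#' `prune_alpha`.
#'
#' @param table Configuration results `data.frame` (see
#'   [write_results_table()]); the response is its `score` column.
#' @param factors Character vector of three factor column names (default
#'   representation, strategy, atlas).
#' @param prune_alpha Interaction retention threshold (default 0.001).
#' @param response Response column name (default `"score"`).
#' @return List with elements `full` and `pruned`, both `anova_table`s
#'   (term data.frame with `sum_sq`, `df`, `F`, `p`, plus the residual
#'   line).
#' @export
three_way_anova <- function(table, factors = c("representation", "strategy", "atlas"),
                            prune_alpha = 0.001, response = "score") {
  stopifnot(is.data.frame(table), length(factors) >= 1L,
            all(c(factors, response) %in% names(table)))
  for (f in factors) {
    if (length(unique(table[[f]])) < 2L) {
      stop_dc("factor `%s` has fewer than 2 observed levels", f,
              class = "dynconn_design_error")
    }
  }
  full_formula <- as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  full <- fit_type3(table, full_formula)
  if (full$residual$df < 1) {
    stop_dc("no residual degrees of freedom for the full model",
            class = "dynconn_design_error")
  }
  inter <- full$terms$term[grepl(":", full$terms$term)]
  keep_inter <- inter[full$terms$p[match(inter, full$terms$term)] <= prune_alpha]
  pruned_formula <- as.formula(paste(
    response, "~", paste(c(factors, keep_inter), collapse = " + ")))
  pruned <- fit_type3(table, pruned_formula)
  list(full = full, pruned = pruned)
}

#' Per-level means and pairwise differences for one factor
#'
#' @param table Configuration results `data.frame`.
#' @param factor_name Column to summarise by.
#' @param response Response column (default `"score"`).
#' @return List with `means` (data.frame: level, mean, n) and
#'   `differences` (data.frame: level_a, level_b, difference =
#'   mean_a - mean_b, signed).
#' @export
factor_effect_summary <- function(table, factor_name, response = "score") {
  stopifnot(all(c(factor_name, response) %in% names(table)))
  ag <- aggregate(table[[response]], by = list(level = table[[factor_name]]),
                  FUN = mean)
  n <- aggregate(table[[response]], by = list(level = table[[factor_name]]),
                 FUN = length)
  means <- data.frame(level = as.character(ag$level), mean = ag$x, n = n$x,
                      stringsAsFactors = FALSE)
  means <- means[order(means$level), , drop = FALSE]
  rownames(means) <- NULL
  if (nrow(means) < 2L) {
    diffs <- data.frame(level_a = character(0), level_b = character(0),
                        difference = numeric(0))
  } else {
    cmb <- combn(nrow(means), 2L)
    diffs <- data.frame(
      level_a = means$level[cmb[1L, ]],
      level_b = means$level[cmb[2L, ]],
      difference = means$mean[cmb[1L, ]] - means$mean[cmb[2L, ]],
      stringsAsFactors = FALSE)
  }
  list(means = means, differences = diffs)
}

# Split a canonical feature name into its two region endpoints, dropping
# any _wk/_st suffix.  Errors on malformed names.
parse_feature_regions <- function(name) {
  base <- sub("_(wk|st)$", "", name)
  parts <- strsplit(base, "__", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || any(parts == "")) {
    stop_dc("malformed feature name `%s` (expected Ri__Rj[_wk|_st])", name,
            class = "dynconn_parse_error")
  }
  parts
}

#' Region frequency among selected features
#'
#' Each selected feature contributes one count to both of its endpoint
#' regions.  Regions are ranked by descending count, ties broken
#' alphabetically.
#'
#' @param selected_names Character vector of canonical feature names
#'   (`Ri__Rj`, optionally suffixed `_wk`/`_st`).
#' @return `data.frame` with columns `region`, `count`, ranked.
#' @export
region_frequency <- function(selected_names) {
  if (length(selected_names) == 0L) {
    return(data.frame(region = character(0), count = integer(0)))
  }
  regions <- unlist(lapply(selected_names, parse_feature_regions))
  tab <- table(regions)
  out <- data.frame(region = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weak/strong proportions among selected dynamic features
#'
#' The share of selected dFC features quantifying under-connectivity
#' (`_wk`) versus over-connectivity (`_st`); the two fractions sum to 1.
#'
#' @param selected_names Character vector of dFC feature names (every name
#'   must end in `_wk` or `_st`).
#' @return Named numeric vector `c(wk_fraction = ..., st_fraction = ...)`.
#' @export
wk_st_proportions <- function(selected_names) {
  if (length(selected_names) == 0L) {
    stop_dc("empty selected-feature list", class = "dynconn_value_error")
  }
  is_wk <- grepl("_wk$", selected_names)
  is_st <- grepl("_st$", selected_names)
  if (!all(is_wk | is_st)) {
    stop_dc("feature name(s) without _wk/_st suffix (static FC names?): %s",
            paste(head(selected_names[!(is_wk | is_st)], 3L), collapse = ", "),
            class = "dynconn_value_error")
  }
  c(wk_fraction = mean(is_wk), st_fraction = mean(is_st))
}
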