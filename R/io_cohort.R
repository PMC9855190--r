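# Cohort I/O: ROI time-series files, phenotype CSVs, atlas label lists,
# and the long-format configuration-results table.

#' Construct a ROI time-series object
#'
#' The basic per-subject container: a T x A matrix of region-mean BOLD
#' values (rows = volumes in acquisition order, columns = atlas regions),
#' plus the repetition time and the labels naming the regions.
#'
#' Region columns containing some non-finite entries are mean-imputed (with
#' a warning) so that the region count A stays fixed across a cohort;
#' a fully non-finite column is an error.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param data Numeric matrix, T rows (volumes) by A columns (regions),
#'   T >= 2, A >= 2.
#' @param tr_seconds Repetition time in seconds, in (0, 10).
#' @param region_labels Character vector of length A naming the regions.
#' @param strategy_tag Preprocessing strategy label, one of
#'   `"filt_global"`, `"filt_noglobal"`, `"nofilt_global"`,
#'   `"nofilt_noglobal"`.
#' @param atlas_tag Atlas label, `"AAL"` or `"TT"`.
#' @return An object of class `roi_time_series`.
#' @export
roi_time_series <- function(subject_id, data, tr_seconds, region_labels,
                            strategy_tag = "filt_global", atlas_tag = "AAL") {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_dc("`data` must be a numeric matrix", class = "dynconn_schema_error")
  }
  if (nrow(data) < 2L || ncol(data) < 2L) {
    stop_dc("ROI series needs at least 2 volumes and 2 regions (got %d x %d)",
            nrow(data), ncol(data), class = "dynconn_schema_error")
  }
  assert_scalar_number(tr_seconds, "tr_seconds", lower = 1e-9, upper = 10 - 1e-9)
  region_labels <- as.character(region_labels)
  if (length(region_labels) != ncol(data)) {
    stop_dc("%d region labels for %d data columns (subject %s)",
            length(region_labels), ncol(data), subject_id,
            class = "dynconn_schema_error")
  }
  strategy_tag <- match.arg(strategy_tag, STRATEGY_LEVELS)
  atlas_tag <- match.arg(atlas_tag, ATLAS_LEVELS)
  bad <- !is.finite(data)
  if (any(bad)) {
    dead <- colSums(bad) == nrow(data)
    if (any(dead)) {
      stop_dc("region column(s) entirely non-finite: %s (subject %s)",
              paste(region_labels[dead], collapse = ", "), subject_id,
              class = "dynconn_value_error")
    }
    for (j in which(colSums(bad) > 0L)) {
      data[bad[, j], j] <- mean(data[!bad[, j], j])
    }
    warning(sprintf("subject %s: %d non-finite value(s) mean-imputed per region",
                    subject_id, sum(bad)), call. = FALSE)
  }
  colnames(data) <- region_labels
  structure(
    list(subject_id = subject_id, data = data, tr_seconds = tr_seconds,
         region_labels = region_labels, strategy_tag = strategy_tag,
         atlas_tag = atlas_tag),
    class = "roi_time_series")
}

#' @export
print.roi_time_series <- function(x, ...) {
  cat(sprintf("<roi_time_series> subject %s: %d volumes x %d regions, TR %.3gs, %s/%s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              x$atlas_tag, x$strategy_tag))
  invisible(x)
}

#' @export
dim.roi_time_series <- function(x) dim(x$data)

#' Read a whitespace-delimited ROI time-series file
#'
#' Reads the plain-text ROI-series dialect used by the ABIDE preprocessed
#' release (`.1D`/`.tsv`): one row per volume, one column per region,
#' optionally preceded by a single header row of region names.  Header
#' names, when present, take precedence over `labels`.
#'
#' @param path Path to the file.
#' @param tr_seconds Repetition time in seconds.
#' @param labels Character vector of region names; required when the file
#'   has no header.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param strategy_tag,atlas_tag Metadata tags, see [roi_time_series()].
#' @param transposed Set `TRUE` for files stored region-by-time; the matrix
#'   is transposed after parsing.
#' @return A [roi_time_series()] object.
#' @export
read_roi_series <- function(path, tr_seconds, labels = NULL,
                            subject_id = sub("\\.[^.]*$", "", basename(path)),
                            strategy_tag = "filt_global", atlas_tag = "AAL",
                            transposed = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    stop_dc("%s: no data rows", path, class = "dynconn_parse_error")
  }
  toks <- strsplit(trimws(lines), "[ \t,]+")
  header <- NULL
  first <- suppressWarnings(as.numeric(toks[[1L]]))
  if (anyNA(first)) {
    header <- toks[[1L]]
    toks <- toks[-1L]
    if (length(toks) == 0L) {
      stop_dc("%s: header but no data rows", path, class = "dynconn_parse_error")
    }
  }
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    stop_dc("%s: ragged row %d (%d fields, expected %d)", path,
            bad + !is.null(header), ncols[bad], ncols[1L],
            class = "dynconn_parse_error")
  }
  vals <- suppressWarnings(vapply(toks, as.numeric, numeric(ncols[1L])))
  vals <- if (ncols[1L] == 1L) matrix(vals, ncol = 1L) else t(vals)
  na_cell <- which(is.na(vals) & t(vapply(toks, function(tk) !(tk %in% c("NA", "NaN", "nan")), logical(ncols[1L]))), arr.ind = TRUE)
  if (nrow(na_cell) > 0L) {
    stop_dc("%s: non-numeric value at data row %d, column %d", path,
            na_cell[1L, 1L], na_cell[1L, 2L], class = "dynconn_parse_error")
  }
  if (transposed) vals <- t(vals)
  use_labels <- header %||% labels
  if (is.null(use_labels)) {
    stop_dc("%s: no header row and no `labels` supplied", path,
            class = "dynconn_schema_error")
  }
  if (length(use_labels) != ncol(vals)) {
    stop_dc("%s: %d region labels for %d columns", path, length(use_labels),
            ncol(vals), class = "dynconn_schema_error")
  }
  roi_time_series(subject_id, vals, tr_seconds, use_labels,
                  strategy_tag = strategy_tag, atlas_tag = atlas_tag)
}

#' Write a ROI time series to a plain-text file
#'
#' Inverse of [read_roi_series()]: a header row of region names followed by
#' one whitespace-delimited row per volume.
#'
#' @param ts A [roi_time_series()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_series <- function(ts, path) {
  stopifnot(inherits(ts, "roi_time_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ts$region_labels, collapse = "\t"), con)
  write.table(ts$data, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an atlas region-label list
#'
#' One region name per line; blank lines and `#` comments are skipped.
#'
#' @param path Path to the label file.
#' @return Character vector of region names.
#' @export
read_atlas_labels <- function(path) {
  x <- trimws(readLines(path))
  x[!grepl("^(#|$)", x)]
}

#' Read a phenotype table
#'
#' Reads a CSV of per-subject phenotypes in the ABIDE dialect: numeric
#' diagnosis codes (default 1 = ASD, 2 = TD) and sex codes (1 = M, 2 = F).
#' Column names and code maps are configurable via `columns`, `dx_map` and
#' `sex_map`.  Rows with a missing/unmappable diagnosis are dropped with a
#' warning; duplicate subject ids are an error; missing FIQ is kept as `NA`.
#'
#' @param path Path to the CSV file.
#' @param columns Named character vector mapping the roles
#'   `subject_id`, `dx`, `site`, `age_years`, `sex`, `fiq` to column names
#'   in the file.
#' @param dx_map,sex_map Named character vectors mapping raw codes (as
#'   strings) to `ASD`/`TD` and `M`/`F`.
#' @return A `data.frame` of class `phenotype_table` with columns
#'   `subject_id`, `dx`, `site`, `age_years`, `sex`, `fiq`.
#' @export
read_phenotype <- function(path,
                           columns = c(subject_id = "SUB_ID", dx = "DX_GROUP",
                                       site = "SITE_ID", age_years = "AGE_AT_SCAN",
                                       sex = "SEX", fiq = "FIQ"),
                           dx_map = c("1" = "ASD", "2" = "TD"),
                           sex_map = c("1" = "M", "2" = "F")) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(columns[c("subject_id", "dx")], names(raw))
  if (length(missing_cols) > 0L) {
    stop_dc("%s: required column(s) missing: %s", path,
            paste(missing_cols, collapse = ", "), class = "dynconn_schema_error")
  }
  get_col <- function(role, default = NA) {
    cn <- columns[[role]]
    if (!is.null(cn) && cn %in% names(raw)) raw[[cn]] else rep(default, nrow(raw))
  }
  dx <- unname(dx_map[as.character(get_col("dx"))])
  drop <- is.na(dx)
  if (any(drop)) {
    warning(sprintf("%s: %d row(s) dropped for missing/unknown diagnosis",
                    path, sum(drop)), call. = FALSE)
  }
  out <- data.frame(
    subject_id = as.character(get_col("subject_id")),
    dx = dx,
    site = as.character(get_col("site", "unknown")),
    age_years = suppressWarnings(as.numeric(get_col("age_years"))),
    sex = unname(sex_map[as.character(get_col("sex"))]),
    fiq = suppressWarnings(as.numeric(get_col("fiq"))),
    stringsAsFactors = FALSE)
  out <- out[!drop, , drop = FALSE]
  if (anyDuplicated(out$subject_id)) {
    stop_dc("%s: duplicate subject id(s): %s", path,
            paste(unique(out$subject_id[duplicated(out$subject_id)]), collapse = ", "),
            class = "dynconn_schema_error")
  }
  bad_age <- !is.na(out$age_years) & out$age_years < 0
  if (any(bad_age)) {
    stop_dc("%s: negative age for subject(s) %s", path,
            paste(out$subject_id[bad_age], collapse = ", "),
            class = "dynconn_value_error")
  }
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a phenotype table as ABIDE-dialect CSV
#'
#' @param phenotypes A `phenotype_table` (see [read_phenotype()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(phenotypes, path) {
  out <- data.frame(
    SUB_ID = phenotypes$subject_id,
    DX_GROUP = match(phenotypes$dx, c("ASD", "TD")),
    SITE_ID = phenotypes$site,
    AGE_AT_SCAN = phenotypes$age_years,
    SEX = match(phenotypes$sex, c("M", "F")),
    FIQ = phenotypes$fiq)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a cohort from subjects and phenotypes
#'
#' Validates that every subject has a phenotype row and that all subjects
#' share the same atlas and region-label ordering (feature names must align
#' across the cohort).
#'
#' @param subjects List of [roi_time_series()] objects.
#' @param phenotypes A `phenotype_table`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, phenotypes) {
  stopifnot(is.list(subjects), length(subjects) >= 1L,
            all(vapply(subjects, inherits, logical(1), "roi_time_series")))
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  missing <- setdiff(ids, phenotypes$subject_id)
  if (length(missing) > 0L) {
    stop_dc("no phenotype for subject(s): %s", paste(missing, collapse = ", "),
            class = "dynconn_schema_error")
  }
  atl <- unique(vapply(subjects, `[[`, character(1), "atlas_tag"))
  if (length(atl) != 1L) {
    stop_dc("subjects mix atlases: %s", paste(atl, collapse = ", "),
            class = "dynconn_schema_error")
  }
  ref <- subjects[[1L]]$region_labels
  same <- vapply(subjects, function(s) identical(s$region_labels, ref), logical(1))
  if (!all(same)) {
    stop_dc("subject(s) %s have different region labels/order",
            paste(ids[!same], collapse = ", "), class = "dynconn_schema_error")
  }
  phen <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  rownames(phen) <- NULL
  structure(list(subjects = subjects, phenotypes = phen), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(x$subjects)
  cat(sprintf("<cohort> %d subjects (%d ASD / %d TD), %d regions, atlas %s\n",
              n, sum(x$phenotypes$dx == "ASD"), sum(x$phenotypes$dx == "TD"),
              length(x$subjects[[1L]]$region_labels), x$subjects[[1L]]$atlas_tag))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$subjects)

#' Diagnosis labels of a cohort
#'
#' @param x A [cohort()].
#' @return Factor with levels `TD`, `ASD` (ASD is the positive class), in
#'   subject order.
#' @export
cohort_labels <- function(x) {
  factor(x$phenotypes$dx, levels = c("TD", "ASD"))
}

#' Write a cohort to a directory in the on-disk formats
#'
#' One ROI-series text file per subject (`<subject_id>.tsv`) plus a
#' `phenotype.csv` in the ABIDE dialect.
#'
#' @param x A [cohort()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in x$subjects) {
    write_roi_series(s, file.path(dir, paste0(s$subject_id, ".tsv")))
  }
  write_phenotype(x$phenotypes, file.path(dir, "phenotype.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `*.tsv` ROI series and `phenotype.csv`.
#' @param tr_seconds Repetition time for all subjects.
#' @param strategy_tag,atlas_tag Metadata tags for the read series.
#' @return A [cohort()].
#' @export
read_cohort <- function(dir, tr_seconds = 2, strategy_tag = "filt_global",
                        atlas_tag = "AAL") {
  files <- sort(list.files(dir, pattern = "\\.(tsv|1D)$", full.names = TRUE))
  if (length(files) == 0L) {
    stop_dc("%s: no ROI series files", dir, class = "dynconn_parse_error")
  }
  phen <- read_phenotype(file.path(dir, "phenotype.csv"))
  subjects <- lapply(files, read_roi_series, tr_seconds = tr_seconds,
                     strategy_tag = strategy_tag, atlas_tag = atlas_tag)
  cohort(subjects, phen)
}

# ---- configuration results table ----------------------------------------

RESULTS_FACTORS <- c(feat = "representation", atls = "atlas", strat = "strategy",
                     kernel = "kernel", classifier = "classifier")

results_factor_levels <- list(
  representation = REPRESENTATION_LEVELS,
  atlas = ATLAS_LEVELS,
  strategy = STRATEGY_LEVELS,
  kernel = KERNEL_LEVELS,
  classifier = CLASSIFIER_LEVELS)

validate_results_table <- function(tab, where = "results table") {
  need <- c(names(results_factor_levels), "score")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop_dc("%s: missing column(s) %s", where, paste(missing, collapse = ", "),
            class = "dynconn_schema_error")
  }
  for (f in names(results_factor_levels)) {
    bad <- setdiff(unique(as.character(tab[[f]])), results_factor_levels[[f]])
    if (length(bad) > 0L) {
      stop_dc("%s: unknown %s level(s): %s", where, f,
              paste(bad, collapse = ", "), class = "dynconn_schema_error")
    }
  }
  if (nrow(tab) > 0L && any(!is.finite(tab$score))) {
    stop_dc("%s: non-finite score(s)", where, class = "dynconn_value_error")
  }
  invisible(tab)
}

#' Write / read the long-format configuration results table
#'
#' The results table has one row per pipeline configuration
#' (representation, atlas, strategy, selection kernel, classifier) with its
#' cross-validated scores; it is the input to [three_way_anova()].  The CSV
#' round-trip is lossless; unknown factor levels on read are a schema
#' error.
#'
#' @param table Results `data.frame` (factor columns `representation`,
#'   `atlas`, `strategy`, `kernel`, `classifier`, plus numeric score
#'   columns, `score` mandatory).
#' @param path CSV path.
#' @return `write_results_table()` returns `path` invisibly;
#'   `read_results_table()` returns the validated `data.frame`.
#' @export
write_results_table <- function(table, path) {
  validate_results_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) tab$score <- numeric(0)
  validate_results_table(tab, where = path)
  tab
}
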