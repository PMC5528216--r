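METRICS_COLUMNS <- c("sample_id", "cohort", "adipocyte_area_um2", "ai",
                     "lipid_percent")

#' Read a per-sample metrics table
#'
#' Reads and validates the CSV schema used throughout the package:
#' columns `sample_id`, `cohort`, optional `year`, `adipocyte_area_um2`,
#' `ai`, `lipid_percent`; empty cells are missing values. Cohort labels
#' are normalized case-insensitively to `early`/`late` at this boundary
#' (internally early = 0, late = 1 in the models). Malformed rows are
#' rejected with their line numbers; a missingness summary is reported.
#'
#' @param path CSV path.
#' @param verbose Report per-metric missingness via `message()`.
#' @return Data frame with `cohort` as an early/late factor and numeric
#'   metric columns.
#' @export
read_metrics_table <- function(path, verbose = FALSE) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(METRICS_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$sample_id)) {
    dup <- unique(raw$sample_id[duplicated(raw$sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  }
  coh <- tolower(trimws(raw$cohort))
  bad_coh <- which(!coh %in% c("early", "late"))
  if (length(bad_coh)) {
    stop("invalid cohort label at data row(s) ",
         paste(bad_coh, collapse = ", "),
         " (expected 'early' or 'late', any case)")
  }
  parse_num <- function(col, nm) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop("non-numeric ", nm, " at data row(s) ",
           paste(bad, collapse = ", "))
    }
    out
  }
  out <- data.frame(
    sample_id = raw$sample_id,
    cohort = factor(coh, levels = c("early", "late")),
    adipocyte_area_um2 = parse_num("adipocyte_area_um2", "adipocyte_area_um2"),
    ai = parse_num("ai", "ai"),
    lipid_percent = parse_num("lipid_percent", "lipid_percent")
  )
  if ("year" %in% names(raw)) out$year <- parse_num("year", "year")
  if (verbose) {
    for (m in c("adipocyte_area_um2", "ai", "lipid_percent")) {
      message(sprintf("%s: %d observed / %d rows", m,
                      sum(!is.na(out[[m]])), nrow(out)))
    }
  }
  out
}

#' Write a per-sample metrics table
#'
#' Deterministic column order, empty cells for missing values; reading the
#' file back with [read_metrics_table()] reproduces the input.
#'
#' @param records Metrics data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  cols <- intersect(c(METRICS_COLUMNS, "year"), names(records))
  write.csv(records[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an analysis report to files
#'
#' Writes the tables of an [analyze_metrics_table()] report (or of a bare
#' [run_model_battery()] result) as CSVs with a machine-readable JSON twin
#' per file: `summary.csv`, `correlations.csv`, `models.csv` (one row per
#' model, step and predictor) and `fit_stats.csv` (one row per model).
#'
#' @param report An `adiposity_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "adiposity_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    csv <- file.path(dir, paste0(name, ".csv"))
    js <- file.path(dir, paste0(name, ".json"))
    write.csv(df, csv, row.names = FALSE, na = "")
    jsonlite::write_json(df, js, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
    written <<- c(written, csv, js)
  }
  emit(report$summary, "summary")
  corr <- do.call(rbind, lapply(names(report$correlations), function(nm) {
    r <- report$correlations[[nm]]
    if (is.null(r$r)) return(NULL)
    data.frame(pair = nm, r = r$r, n = r$n, p_value = r$p_value)
  }))
  if (!is.null(corr)) emit(corr, "correlations")
  emit(report$coefficients, "models")
  emit(report$fit_stats, "fit_stats")
  invisible(written)
}
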