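# Reading and writing the long score-sheet CSV format.
#
# Columns: patient_id, scan_id, time_months, observer_id, method, lobe
# (empty for whole-lung/once items), item_id, value.  UTF-8, header
# required.

SHEET_COLUMNS <- c("patient_id", "scan_id", "time_months", "observer_id",
                   "method", "lobe", "item_id", "value")

#' Write score sheets to a long-format CSV
#'
#' @param sheets List of `score_sheet`, or a `sim_cohort` (its observer
#'   sheets are written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sheets <- function(sheets, path) {
  if (inherits(sheets, "sim_cohort")) sheets <- sheets$sheets
  stopifnot(length(sheets) > 0L)
  rows <- do.call(rbind, lapply(sheets, as.data.frame))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read score sheets from a long-format CSV
#'
#' Parses the standard long format, groups rows into one sheet per
#' (patient, scan, observer, method), and validates each sheet against the
#' canonical schema of its method (or `schema` if given).  Rows with
#' non-numeric values are rejected with their line numbers.  In lenient
#' mode (default) invalid sheets are dropped with a warning and the full
#' validation report is attached as attribute `"validation"`; in strict
#' mode any violation is an error.
#'
#' @param path CSV file path.
#' @param schema Optional `scoring_schema` applied to all sheets; by
#'   default each sheet is validated against `canonical_schema(method)`.
#' @param strict Error on any violation instead of dropping sheets.
#' @return List of valid `score_sheet` objects, with attribute
#'   `"validation"` (data frame of all violations; zero rows when clean).
#' @export
read_sheets <- function(path, schema = NULL, strict = FALSE) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(SHEET_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("score-sheet CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  value_num <- suppressWarnings(as.numeric(raw$value))
  time_num <- suppressWarnings(as.numeric(raw$time_months))
  bad_rows <- which(is.na(value_num) | is.na(time_num))
  report <- list()
  if (length(bad_rows)) {
    report[[1L]] <- data.frame(
      patient_id = raw$patient_id[bad_rows], scan_id = raw$scan_id[bad_rows],
      observer_id = raw$observer_id[bad_rows],
      item_id = raw$item_id[bad_rows], lobe = raw$lobe[bad_rows],
      value = raw$value[bad_rows],
      line = bad_rows + 1L,  # account for the header line
      rule = "value or time_months is not numeric", stringsAsFactors = FALSE)
  }
  raw$value <- value_num
  raw$time_months <- time_num
  ok <- setdiff(seq_len(nrow(raw)), bad_rows)
  raw <- raw[ok, , drop = FALSE]

  key <- paste(raw$patient_id, raw$scan_id, raw$observer_id, raw$method,
               sep = "\r")
  groups <- split(seq_len(nrow(raw)), factor(key, levels = unique(key)))
  sheets <- list()
  for (ix in groups) {
    first <- ix[1L]
    sh <- score_sheet(raw$patient_id[first], raw$scan_id[first],
                      raw$time_months[first], raw$observer_id[first],
                      raw$method[first],
                      data.frame(item_id = raw$item_id[ix], lobe = raw$lobe[ix],
                                 value = raw$value[ix],
                                 stringsAsFactors = FALSE))
    sch <- schema %||% canonical_schema(sh$method_name)
    viol <- validate_sheet(sh, sch)
    if (nrow(viol)) {
      viol$patient_id <- sh$patient_id
      viol$scan_id <- sh$scan_id
      viol$observer_id <- sh$observer_id
      report[[length(report) + 1L]] <- viol
    } else {
      sheets[[length(sheets) + 1L]] <- sh
    }
  }
  report_df <- if (length(report)) {
    cols <- unique(unlist(lapply(report, names)))
    do.call(rbind, lapply(report, function(r) {
      for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
      r[cols]
    }))
  } else {
    data.frame(item_id = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  }
  if (nrow(report_df)) {
    if (strict) {
      stop("score-sheet validation failed (", nrow(report_df),
           " violation(s)); first: ", report_df$rule[1L], call. = FALSE)
    }
    warning(nrow(report_df), " violation(s) found; invalid sheets dropped ",
            "(see attr(, 'validation'))", call. = FALSE)
  }
  attr(sheets, "validation") <- report_df
  sheets
}

#' Write the cohort report tables
#'
#' Writes the four tables of [cohort_report()] as CSV files plus a single
#' JSON bundle.
#'
#' @param report Result of [cohort_report()].
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(report)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(report[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  bundle <- file.path(dir, "report.json")
  jsonlite::write_json(report, bundle, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(files, bundle))
}
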