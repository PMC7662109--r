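#' Construct a score sheet
#'
#' A score sheet is one observer's complete item-level scoring of one CT
#' scan under one method.  Values are stored long: one row per scored slot,
#' with `lobe = NA` for whole-lung and once items.
#'
#' @param patient_id,scan_id,observer_id Identifier labels.
#' @param time_months Months since the patient's first analysed scan
#'   (nonnegative).
#' @param method_name `"baumann"` or `"hartmann"`.
#' @param values Data frame with columns `item_id`, `lobe`, `value`.
#' @return A `score_sheet` object.
#' @export
score_sheet <- function(patient_id, scan_id, time_months, observer_id,
                        method_name, values) {
  stopifnot(is.data.frame(values),
            all(c("item_id", "lobe", "value") %in% names(values)))
  values <- data.frame(item_id = tolower(as.character(values$item_id)),
                       lobe = as.character(values$lobe),
                       value = as.numeric(values$value),
                       stringsAsFactors = FALSE)
  values$lobe[!is.na(values$lobe) & values$lobe == ""] <- NA_character_
  structure(
    list(patient_id = as.character(patient_id),
         scan_id = as.character(scan_id),
         time_months = as.numeric(time_months),
         observer_id = as.character(observer_id),
         method_name = tolower(as.character(method_name)),
         values = values),
    class = "score_sheet"
  )
}

#' Build a complete sheet from a named value map
#'
#' Convenience constructor: starts from an all-zero sheet for the schema and
#' overrides the named slots.  Slot names are `item_id` for whole-lung/once
#' items and `item_id.lobe` (e.g. `"ggo_extent.RUL"`) for per-lobe items.
#'
#' @param schema A `scoring_schema`.
#' @param values Named numeric vector of slot overrides (may be empty).
#' @param patient_id,scan_id,time_months,observer_id Sheet metadata.
#' @return A `score_sheet` that is complete with respect to `schema`.
#' @export
sheet_from_values <- function(schema, values = numeric(0), patient_id = "p1",
                              scan_id = "s1", time_months = 0,
                              observer_id = "obs1") {
  slots <- schema_slots(schema)
  v <- numeric(nrow(slots))
  key <- ifelse(is.na(slots$lobe), slots$item_id,
                paste(slots$item_id, slots$lobe, sep = "."))
  if (length(values)) {
    idx <- match(tolower(names(values)), tolower(key))
    if (anyNA(idx)) {
      stop("unknown slot name(s): ",
           paste(names(values)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    v[idx] <- as.numeric(values)
  }
  score_sheet(patient_id, scan_id, time_months, observer_id,
              schema$method_name,
              data.frame(item_id = slots$item_id, lobe = slots$lobe, value = v,
                         stringsAsFactors = FALSE))
}

#' Look up one slot of a sheet
#'
#' @param sheet A `score_sheet`.
#' @param item_id Item identifier.
#' @param lobe Lobe label, or `NULL`/`NA` for whole-lung and once items.
#' @return The numeric value, or `NA` if the slot is absent.
#' @export
sheet_value <- function(sheet, item_id, lobe = NULL) {
  v <- sheet$values
  if (is.null(lobe) || is.na(lobe)) {
    hit <- v$item_id == tolower(item_id) & is.na(v$lobe)
  } else {
    hit <- v$item_id == tolower(item_id) & !is.na(v$lobe) &
      tolower(v$lobe) == tolower(lobe)
  }
  if (!any(hit)) return(NA_real_)
  v$value[which(hit)[1L]]
}

#' @export
print.score_sheet <- function(x, ...) {
  cat(sprintf("<score_sheet> %s | patient %s scan %s (t = %g mo) observer %s\n",
              x$method_name, x$patient_id, x$scan_id, x$time_months,
              x$observer_id))
  cat(sprintf("  %d scored values, %d nonzero\n", nrow(x$values),
              sum(x$values$value != 0)))
  invisible(x)
}

#' @export
as.data.frame.score_sheet <- function(x, ...) {
  data.frame(patient_id = x$patient_id, scan_id = x$scan_id,
             time_months = x$time_months, observer_id = x$observer_id,
             method = x$method_name, lobe = ifelse(is.na(x$values$lobe), "",
                                                   x$values$lobe),
             item_id = x$values$item_id, value = x$values$value,
             stringsAsFactors = FALSE)
}

#' Select each patient's most recent sheet
#'
#' Picks, per patient, the sheet with the largest `time_months`.  Ties on
#' time are broken deterministically by lexicographically largest `scan_id`.
#' Intended for cross-sectional phenotyping where only the most recent scan
#' of each patient is analysed; supply sheets from a single observer.
#'
#' @param sheets List of `score_sheet` objects.
#' @return List of `score_sheet`, one per patient.
#' @export
most_recent_sheets <- function(sheets) {
  stopifnot(length(sheets) > 0L)
  pid <- vapply(sheets, `[[`, "", "patient_id")
  keep <- vapply(split(seq_along(sheets), pid), function(ix) {
    tm <- vapply(sheets[ix], `[[`, 0, "time_months")
    cand <- ix[tm == max(tm)]
    if (length(cand) > 1L) {
      sid <- vapply(sheets[cand], `[[`, "", "scan_id")
      cand <- cand[order(sid, decreasing = TRUE)][1L]
    }
    cand
  }, 0L)
  sheets[sort(unname(keep))]
}
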