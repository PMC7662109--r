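# Inter- and intra-observer agreement.
#
# The agreement statistic is the two-way mixed-effects, single-measurement,
# consistency intraclass correlation coefficient, ICC(C,1):
#
#   ICC(C,1) = (MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)
#
# with mean squares from the two-way ANOVA (subjects x raters, no
# interaction).  Consistency means an additive rater shift does not lower
# the estimate; negative estimates are reported as computed.

#' Subjects-by-raters rating table
#'
#' @param values Numeric matrix, subjects in rows, raters in columns;
#'   complete (no missing cells), at least 2 subjects and 2 raters.
#' @param score_label Label of the score being rated.
#' @return A `rating_table` (a matrix with attributes).
#' @export
rating_table <- function(values, score_label = "score") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("ratings must be numeric", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("rating table needs at least 2 subjects and 2 raters", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("incomplete rating table: missing cells are not supported",
         call. = FALSE)
  }
  structure(values, score_label = score_label, class = c("rating_table",
                                                         class(values)))
}

#' Intraclass correlation coefficient, two-way consistency form
#'
#' Computes ICC(C,1) (default) or the absolute-agreement form ICC(A,1)
#' from the two-way ANOVA mean squares of a complete subjects-by-raters
#' table.  Estimates can be negative and are reported as computed.
#'
#' @param table Numeric subjects-by-raters matrix or [rating_table()].
#' @param type `"consistency"` (default) or `"agreement"` (sensitivity
#'   analysis only).
#' @return An `icc_result`: list with `estimate`, `band`, `n_subjects`,
#'   `k_raters`, `ms_rows`, `ms_error`, `type`, `score_label`.
#' @examples
#' x <- cbind(obs1 = c(1, 2, 3, 5), obs2 = c(2, 3, 5, 8))
#' icc_consistency(x)
#' @export
icc_consistency <- function(table, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  x <- unclass(as.matrix(table))
  label <- attr(table, "score_label") %||% "score"
  if (anyNA(x)) stop("incomplete rating table: missing cells", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }

  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))

  if (ss_tot < 1e-12 || (ss_rows + ss_err) < 1e-12) {
    stop("undefined ICC: no subject or residual variance in the table ",
         "(all ratings equal up to a rater shift)", call. = FALSE)
  }

  est <- if (type == "consistency") {
    (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  } else {
    (ms_rows - ms_err) /
      (ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err))
  }
  structure(
    list(estimate = est, band = icc_band(est), n_subjects = n, k_raters = k,
         ms_rows = ms_rows, ms_error = ms_err, type = type,
         score_label = label),
    class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc> %s: ICC(%s,1) = %.3f [%s]  (n = %d subjects, k = %d raters)\n",
              x$score_label, if (x$type == "consistency") "C" else "A",
              x$estimate, x$band, x$n_subjects, x$k_raters))
  invisible(x)
}

#' Interpretation band of an ICC estimate
#'
#' Banded interpretation: below 0.40 poor, 0.40 to below 0.60 fair, 0.60 to
#' below 0.75 good, 0.75 and above excellent.  Negative estimates are poor.
#'
#' @param estimate Finite numeric ICC estimate(s).
#' @return Character vector of bands.
#' @export
icc_band <- function(estimate) {
  if (any(!is.finite(estimate))) {
    stop("ICC estimate must be finite to band", call. = FALSE)
  }
  cuts <- icc_band_cutoffs()
  ifelse(estimate < cuts[["fair"]], "poor",
         ifelse(estimate < cuts[["good"]], "fair",
                ifelse(estimate < cuts[["excellent"]], "good", "excellent")))
}

#' Lower bounds of the ICC interpretation bands
#'
#' @return Named numeric vector: lowest estimate banded fair, good and
#'   excellent.
#' @export
icc_band_cutoffs <- function() {
  c(fair = 0.40, good = 0.60, excellent = 0.75)
}

# default Table-4-style score panel
AGREEMENT_SCORES <- c("glild", "airway", "nodules", "bronchiectasis",
                      "reticulation", "bronchial_wall_thickening", "ggo",
                      "consolidation", "mucus_plugging")

#' Inter- or intra-observer agreement study
#'
#' Pairs sheets by `scan_id` across two raters (two observers for an
#' inter-observer design; one observer's two scoring sessions, labelled as
#' two rater ids, for an intra-observer design), computes the requested
#' component/composite percent scores, and estimates ICC(C,1) per score.
#' Scans not scored by both raters are listed in a warning and skipped.
#' Scores whose rating table is constant have an undefined ICC and are
#' reported with `estimate = NA`.
#'
#' @param sheets List of `score_sheet` from both raters.
#' @param schema The matching `scoring_schema`.
#' @param raters Character vector of the two `observer_id` labels to
#'   compare; defaults to the two ids present in `sheets`.
#' @param scores Score labels to evaluate (components and/or composites);
#'   defaults to the standard nine-score panel.
#' @param design Label recorded in the output (`"inter"` or `"intra"`).
#' @param exclusions Abnormalities excluded from composites.
#' @return Data frame with one row per score: `score_label`, `design`,
#'   `estimate`, `band`, `n_subjects`, `k_raters`, `ms_rows`, `ms_error`,
#'   `note`.
#' @export
agreement_study <- function(sheets, schema, raters = NULL,
                            scores = AGREEMENT_SCORES,
                            design = c("inter", "intra"),
                            exclusions = "trapped_air") {
  design <- match.arg(design)
  obs <- vapply(sheets, `[[`, "", "observer_id")
  if (is.null(raters)) {
    raters <- unique(obs)
    if (length(raters) != 2L) {
      stop("expected exactly 2 rater labels in the sheets, found ",
           length(raters), "; pass `raters` explicitly", call. = FALSE)
    }
  }
  stopifnot(length(raters) == 2L)
  a <- sheets[obs == raters[1L]]
  b <- sheets[obs == raters[2L]]
  sid_a <- vapply(a, `[[`, "", "scan_id")
  sid_b <- vapply(b, `[[`, "", "scan_id")
  common <- intersect(sid_a, sid_b)
  unpaired <- setdiff(union(sid_a, sid_b), common)
  if (length(unpaired)) {
    warning("skipping scans not scored by both raters: ",
            paste(sort(unpaired), collapse = ", "), call. = FALSE)
  }
  if (length(common) < 2L) {
    stop("fewer than 2 complete rater pairs; cannot estimate agreement",
         call. = FALSE)
  }
  a <- a[match(common, sid_a)]
  b <- b[match(common, sid_b)]

  pct <- function(sheet, label) {
    if (label %in% c("glild", "airway", "total")) {
      composite_score(sheet, label, schema, exclusions)$percent
    } else {
      component_score(sheet, label, schema)$percent
    }
  }
  rows <- lapply(scores, function(label) {
    m <- cbind(vapply(a, pct, 0, label = label),
               vapply(b, pct, 0, label = label))
    res <- tryCatch(icc_consistency(rating_table(m, label)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(score_label = label, design = design, estimate = NA_real_,
                 band = NA_character_, n_subjects = length(common),
                 k_raters = 2L, ms_rows = NA_real_, ms_error = NA_real_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(score_label = label, design = design, estimate = res$estimate,
                 band = res$band, n_subjects = res$n_subjects,
                 k_raters = res$k_raters, ms_rows = res$ms_rows,
                 ms_error = res$ms_error, note = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
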