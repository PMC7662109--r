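# Component and composite scoring.
#
# Both methods express each abnormality as a percent of its maximum possible
# score.  Bronchiectasis and bronchial wall thickening are weighted by a
# severity multiplier before normalisation; all other abnormalities use
# extent only (their severity/qualifier items are carried for reporting).

#' Severity multiplier
#'
#' Tabulated multiplier applied to the extent of bronchiectasis and
#' bronchial wall thickening.  Bronchiectasis grades 1.0, 1.5, 2.0, 2.5,
#' 3.0 map to 1.00, 1.25, 1.50, 1.75, 2.00; bronchial wall thickening
#' grades 1, 2, 3 map to 1.00, 1.25, 1.50.  Grade 0 (abnormality absent)
#' contributes 0.
#'
#' @param abnormality `"bronchiectasis"` or `"bronchial_wall_thickening"`.
#' @param grade Severity grade (may be vectorised).
#' @param schema Schema carrying the multiplier tables; defaults to the
#'   canonical tables (identical in both methods).
#' @return Numeric multiplier(s).
#' @export
multiplier <- function(abnormality, grade,
                       schema = canonical_schema("baumann")) {
  abnormality <- tolower(abnormality)
  tab <- schema$multipliers[[abnormality]]
  if (is.null(tab)) {
    stop("no multiplier table for abnormality '", abnormality, "'",
         call. = FALSE)
  }
  out <- numeric(length(grade))
  nz <- !is.na(grade) & grade != 0
  if (any(nz)) {
    idx <- match(as.character(grade[nz]), names(tab))
    if (anyNA(idx)) {
      bad <- unique(grade[nz][is.na(idx)])
      stop(sprintf("invalid %s severity grade %s (allowed: 0, %s)",
                   abnormality, paste(bad, collapse = ", "),
                   paste(names(tab), collapse = ", ")), call. = FALSE)
    }
    out[nz] <- unname(tab[idx])
  }
  out[is.na(grade)] <- NA_real_
  out
}

# abnormalities that have an extent item and therefore a component score
.component_abnormalities <- function(schema) {
  ext <- schema$items$value_kind %in% c("extent_lobe_count", "extent_grade")
  unique(schema$items$abnormality[ext])
}

#' Component score of one abnormality
#'
#' Computes the raw score, the maximum possible score, and the percent of
#' maximum for a single abnormality on one sheet.
#'
#' Baumann: raw = extent (number of affected lobes, 0-6); for
#' bronchiectasis and bronchial wall thickening raw = extent x
#' multiplier(severity), max = 6 x multiplier(top grade).  Hartmann: raw is
#' summed over the six lobes; weighted items use per-lobe extent x
#' multiplier(per-lobe severity), max = 6 x 3 x multiplier(top grade);
#' unweighted items use extent only, max = 18.
#'
#' @param sheet A valid `score_sheet`.
#' @param abnormality Abnormality label (e.g. `"ggo"`).
#' @param schema The matching `scoring_schema`.
#' @return A `component_result`: list with `abnormality`, `raw_score`,
#'   `max_score`, `percent`.
#' @examples
#' sch <- canonical_schema("baumann")
#' sh <- sheet_from_values(sch, c(bronchiectasis_extent = 3,
#'                                bronchiectasis_severity = 2))
#' component_score(sh, "bronchiectasis", sch)$percent  # 37.5
#' @export
component_score <- function(sheet, abnormality, schema) {
  abnormality <- tolower(abnormality)
  if (!abnormality %in% .component_abnormalities(schema)) {
    stop("unknown abnormality '", abnormality, "' for the ",
         schema$method_name, " method", call. = FALSE)
  }
  weighted <- abnormality %in% names(schema$multipliers)
  v <- sheet$values
  if (schema$method_name == "baumann") {
    extent <- v$value[v$item_id == paste0(abnormality, "_extent")][1L]
    if (weighted) {
      sev <- v$value[v$item_id == paste0(abnormality, "_severity")][1L]
      tab <- schema$multipliers[[abnormality]]
      raw <- extent * multiplier(abnormality, sev, schema)
      max_score <- 6 * max(tab)
    } else {
      raw <- extent
      max_score <- 6
    }
  } else {
    extent <- v$value[v$item_id == paste0(abnormality, "_extent")]
    if (weighted) {
      sev <- v$value[v$item_id == paste0(abnormality, "_severity")]
      tab <- schema$multipliers[[abnormality]]
      raw <- sum(extent * multiplier(abnormality, sev, schema))
      max_score <- 6 * 3 * max(tab)
    } else {
      raw <- sum(extent)
      max_score <- 6 * 3
    }
  }
  structure(list(abnormality = abnormality, raw_score = raw,
                 max_score = max_score, percent = 100 * raw / max_score),
            class = "component_result")
}

.composite_constituents <- function(name, schema,
                                    exclusions = "trapped_air") {
  name <- tolower(name)
  if (!name %in% c("glild", "airway", "total")) {
    stop("unknown composite '", name,
         "' (supported: glild, airway, total)", call. = FALSE)
  }
  ext <- schema$items[schema$items$value_kind %in%
                        c("extent_lobe_count", "extent_grade"), ]
  member <- vapply(ext$composites, function(cc) name %in% cc, NA)
  abns <- unique(ext$abnormality[member])
  setdiff(abns, tolower(exclusions))
}

#' Composite score (GLILD, airway disease, total disease)
#'
#' GLILD combines GGO, nodules and reticulation; airway disease combines
#' bronchial wall thickening, bronchiectasis and mucus plugging; total
#' disease sums all extent-scored abnormalities.  The composite raw score
#' and maximum are the exact sums of the constituents', and the percent is
#' 100 x raw / max.
#'
#' @param sheet A valid `score_sheet`.
#' @param name `"glild"`, `"airway"` or `"total"`.
#' @param schema The matching `scoring_schema`.
#' @param exclusions Abnormalities dropped from the composite.  Defaults to
#'   trapped air, which the scoring protocol excludes when no expiratory
#'   acquisitions are available.
#' @return A `composite_result`: list with `name`, `raw_score`, `max_score`,
#'   `percent`, `constituents` (list of `component_result`).
#' @export
composite_score <- function(sheet, name, schema, exclusions = "trapped_air") {
  abns <- .composite_constituents(name, schema, exclusions)
  parts <- lapply(abns, function(a) component_score(sheet, a, schema))
  raw <- sum(vapply(parts, `[[`, 0, "raw_score"))
  max_score <- sum(vapply(parts, `[[`, 0, "max_score"))
  structure(list(name = tolower(name), raw_score = raw, max_score = max_score,
                 percent = 100 * raw / max_score, constituents = parts),
            class = "composite_result")
}

#' @export
print.component_result <- function(x, ...) {
  cat(sprintf("<component> %s: %.4g / %.4g = %.1f%%\n", x$abnormality,
              x$raw_score, x$max_score, x$percent))
  invisible(x)
}

#' @export
print.composite_result <- function(x, ...) {
  cat(sprintf("<composite> %s: %.4g / %.4g = %.1f%% (%d constituents)\n",
              x$name, x$raw_score, x$max_score, x$percent,
              length(x$constituents)))
  invisible(x)
}

#' All component and composite percents of a sheet
#'
#' @param sheet A valid `score_sheet`.
#' @param schema The matching `scoring_schema`.
#' @param exclusions Abnormalities excluded from composites (default trapped
#'   air).
#' @return Data frame with columns `score_label`, `kind`, `raw_score`,
#'   `max_score`, `percent`.
#' @export
score_table <- function(sheet, schema, exclusions = "trapped_air") {
  abns <- setdiff(.component_abnormalities(schema), tolower(exclusions))
  comp <- lapply(abns, function(a) component_score(sheet, a, schema))
  cmps <- lapply(c("glild", "airway", "total"),
                 function(n) composite_score(sheet, n, schema, exclusions))
  data.frame(
    score_label = c(abns, "glild", "airway", "total"),
    kind = c(rep("component", length(abns)), rep("composite", 3L)),
    raw_score = c(vapply(comp, `[[`, 0, "raw_score"),
                  vapply(cmps, `[[`, 0, "raw_score")),
    max_score = c(vapply(comp, `[[`, 0, "max_score"),
                  vapply(cmps, `[[`, 0, "max_score")),
    percent = c(vapply(comp, `[[`, 0, "percent"),
                vapply(cmps, `[[`, 0, "percent")),
    stringsAsFactors = FALSE
  )
}

#' Radiological phenotype of one scan
#'
#' Derives the GLILD and airway-disease flags, the set of GLILD features
#' present, the enlarged-lymph-node flag (measured mm >= threshold for
#' Baumann, scored presence for Hartmann), and the maximal severity per
#' abnormality.
#'
#' @param sheet A valid `score_sheet`.
#' @param schema The matching `scoring_schema`.
#' @param ln_threshold_mm Short-axis diameter defining an enlarged lymph
#'   node for the Baumann measurement, in mm (default 10).
#' @return A `phenotype_record`: list with `patient_id`, `scan_id`,
#'   `glild_positive`, `airway_positive`, `glild_features_present`,
#'   `lymphadenopathy_enlarged`, `max_severity`.
#' @export
phenotype <- function(sheet, schema, ln_threshold_mm = 10) {
  glild_feats <- c("ggo", "nodules", "reticulation")
  feat_pos <- vapply(glild_feats, function(a)
    component_score(sheet, a, schema)$percent > 0, NA)
  airway <- composite_score(sheet, "airway", schema)

  if (schema$method_name == "baumann") {
    ln <- sheet_value(sheet, "lymph_node_mm")
    ln_enlarged <- is.finite(ln) && ln >= ln_threshold_mm
    max_sev <- list(
      bronchiectasis = sheet_value(sheet, "bronchiectasis_severity"),
      bronchial_wall_thickening =
        sheet_value(sheet, "bronchial_wall_thickening_severity"),
      nodule_size = sheet_value(sheet, "nodule_size_category")
    )
  } else {
    ln_enlarged <- isTRUE(sheet_value(sheet, "lymphadenopathy_presence") == 1)
    v <- sheet$values
    max_sev <- list(
      bronchiectasis = max(v$value[v$item_id == "bronchiectasis_severity"]),
      bronchial_wall_thickening =
        max(v$value[v$item_id == "bronchial_wall_thickening_severity"]),
      # per-scan nodule size is reported as the maximum per-lobe grade
      nodule_size = max(v$value[v$item_id == "nodules_severity"])
    )
  }
  structure(
    list(patient_id = sheet$patient_id, scan_id = sheet$scan_id,
         glild_positive = any(feat_pos),
         airway_positive = airway$percent > 0,
         glild_features_present = glild_feats[feat_pos],
         lymphadenopathy_enlarged = ln_enlarged,
         max_severity = max_sev),
    class = "phenotype_record"
  )
}

#' @export
print.phenotype_record <- function(x, ...) {
  cat(sprintf("<phenotype> patient %s scan %s: GLILD %s (%s), airway %s, enlarged LN %s\n",
              x$patient_id, x$scan_id,
              if (x$glild_positive) "positive" else "negative",
              paste(x$glild_features_present, collapse = "+"),
              if (x$airway_positive) "positive" else "negative",
              x$lymphadenopathy_enlarged))
  invisible(x)
}

# group bronchiectasis half grades into the three airway/vessel categories
.severity_category <- function(grade) {
  ifelse(grade <= 0, 0L, ifelse(grade < 2, 1L, ifelse(grade < 3, 2L, 3L)))
}

#' Cross-sectional cohort report
#'
#' Given one most-recent sheet per patient (see [most_recent_sheets()]),
#' produces the four standard cohort tables: (a) prevalence of each
#' component and composite (n and percent of patients with a positive
#' score, sorted descending); (b) maximal-severity distribution among
#' positives for bronchiectasis, bronchial wall thickening and nodule size;
#' (c) median, interquartile range and min-max of each percent score;
#' (d) counts of the seven GLILD feature combinations (GGO / nodules /
#' reticulation Venn regions) among GLILD-positive patients.
#'
#' Percent columns in the output are rounded to whole percents; the
#' score-distribution table keeps one decimal.
#'
#' @param sheets List of `score_sheet`, one per patient.
#' @param schema The matching `scoring_schema`.
#' @param exclusions Abnormalities excluded from composites.
#' @param ln_threshold_mm Enlarged-lymph-node threshold passed to
#'   [phenotype()].
#' @return List of data frames `prevalence`, `severity`, `distribution`,
#'   `venn`.
#' @export
cohort_report <- function(sheets, schema, exclusions = "trapped_air",
                          ln_threshold_mm = 10) {
  if (length(sheets) == 0L) {
    stop("empty cohort: no score sheets supplied", call. = FALSE)
  }
  tabs <- lapply(sheets, score_table, schema = schema, exclusions = exclusions)
  labels <- tabs[[1L]]$score_label
  pct <- vapply(tabs, `[[`, numeric(length(labels)), "percent")
  pct <- matrix(pct, nrow = length(labels))  # labels x patients
  n <- length(sheets)

  pos <- rowSums(pct > 0)
  prevalence <- data.frame(
    score_label = labels, n_positive = as.integer(pos),
    n_patients = n, percent_positive = round(100 * pos / n),
    stringsAsFactors = FALSE)
  prevalence <- prevalence[order(-prevalence$n_positive, prevalence$score_label), ]
  rownames(prevalence) <- NULL

  phen <- lapply(sheets, phenotype, schema = schema,
                 ln_threshold_mm = ln_threshold_mm)
  sev_rows <- list()
  sev_spec <- list(
    bronchiectasis = function(p) .severity_category(p$max_severity$bronchiectasis),
    bronchial_wall_thickening =
      function(p) p$max_severity$bronchial_wall_thickening,
    nodule_size = function(p) p$max_severity$nodule_size)
  for (nm in names(sev_spec)) {
    g <- vapply(phen, sev_spec[[nm]], 0)
    g <- g[g > 0]
    for (cat in 1:3) {
      sev_rows[[length(sev_rows) + 1L]] <- data.frame(
        abnormality = nm, category = cat, n = sum(g == cat),
        n_positive = length(g),
        percent_within_positive =
          if (length(g)) round(100 * sum(g == cat) / length(g)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  severity <- do.call(rbind, sev_rows)

  distribution <- data.frame(
    score_label = labels,
    median = round(apply(pct, 1L, median), 1),
    q1 = round(apply(pct, 1L, quantile, 0.25), 1),
    q3 = round(apply(pct, 1L, quantile, 0.75), 1),
    min = round(apply(pct, 1L, min), 1),
    max = round(apply(pct, 1L, max), 1),
    stringsAsFactors = FALSE)

  glild_pos <- Filter(function(p) p$glild_positive, phen)
  feats <- c("ggo", "nodules", "reticulation")
  combos <- expand.grid(ggo = c(FALSE, TRUE), nodules = c(FALSE, TRUE),
                        reticulation = c(FALSE, TRUE))
  combos <- combos[rowSums(combos) > 0, ]
  venn <- data.frame(
    region = apply(combos, 1L, function(r) paste(feats[as.logical(r)],
                                                 collapse = "+")),
    n = vapply(seq_len(nrow(combos)), function(i) {
      want <- feats[as.logical(combos[i, ])]
      sum(vapply(glild_pos, function(p)
        setequal(p$glild_features_present, want), NA))
    }, 0L),
    stringsAsFactors = FALSE)
  venn$n_glild_positive <- length(glild_pos)
  rownames(venn) <- NULL

  list(prevalence = prevalence, severity = severity,
       distribution = distribution, venn = venn)
}
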