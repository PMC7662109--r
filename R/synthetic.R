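# Synthetic observer score-sheet cohorts with known ground truth.
#
# The generator emulates the shape of a retrospective GLILD CT cohort:
# per-abnormality prevalence, ordinal severity distributions, lobar spread,
# repeated scans at roughly yearly intervals, slow latent progression, and
# two observers whose disagreement is concentrated on adjacent grades.
# Ground truth (noise-free sheets and their scores) is returned alongside,
# so scoring, agreement and longitudinal analyses can be checked against
# known answers.

# deterministic per-patient substream: cohort growth never reshuffles
# earlier patients (double arithmetic to avoid 32-bit overflow)
.patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i) %% 2147483629)
}

.default_prevalence <- c(
  bronchiectasis = 0.82, bronchial_wall_thickening = 0.67,
  mucus_plugging = 0.45, atelectasis = 0.30, nodules = 0.76,
  reticulation = 0.65, consolidation = 0.35, ggo = 0.70, cysts = 0.10,
  emphysema_bullae = 0.12, emphysema = 0.12, bullae = 0.08,
  scars_bands = 0.30, trapped_air = 0.20, distortion = 0.20,
  lymphadenopathy = 0.50)

.default_severity <- function() {
  list(
    bronchiectasis = list(grades = c(1, 1.5, 2, 2.5, 3),
                          probs = c(0.50, 0.30, 0.10, 0.06, 0.04)),
    bronchial_wall_thickening = list(grades = c(1, 2, 3),
                                     probs = c(0.85, 0.14, 0.01)),
    nodule_size = list(grades = c(1, 2, 3), probs = c(0.16, 0.43, 0.41)),
    default = list(grades = c(1, 2, 3), probs = c(0.60, 0.30, 0.10)))
}

#' Simulation configuration
#'
#' Defines a synthetic cohort: number of patients, visit model (scans per
#' patient over 1-9 and log-normal inter-scan gaps in months),
#' per-abnormality prevalence and latent severity distributions, lobar
#' spread probability, observer model (adjacent-grade confusion
#' probability, per-observer direction bias, measurement noise), and latent
#' drift per month.
#'
#' @param seed Master seed; per-patient substreams are derived from it so
#'   growing the cohort does not reshuffle existing patients.
#' @param method `"baumann"` or `"hartmann"`.
#' @param n_patients Number of patients.
#' @param visit List: `counts` (possible scans per patient, within 1-9),
#'   `probs` (their probabilities), `n_single` (this many patients, taken
#'   first, get exactly one scan; the rest draw from `counts`/`probs`),
#'   `gap_meanlog`, `gap_sdlog` (log-normal inter-scan gap, months).
#' @param prevalence Named per-abnormality probabilities in `[0, 1]`.
#' @param severity_dist Named list of `list(grades, probs)`; the `default`
#'   entry covers abnormalities without their own.
#' @param extent_grade_dist Probabilities of per-lobe extent grades 1-3
#'   (Hartmann).
#' @param lobe_involvement Probability that each lobe of a diseased patient
#'   is involved (at least one lobe is always involved).
#' @param observer List: `n` observers, `confusion` (probability that an
#'   ordinal value moves to an adjacent grade), `bias` (per-observer
#'   probability shift toward the upper neighbour, in `[-0.45, 0.45]`),
#'   `mm_sd` (SD of measurement noise on mm items).
#' @param drift_per_month Named latent extent drift per month (lobe-count
#'   units for Baumann, per-lobe grade units for Hartmann); bounded at the
#'   scale limits.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, method = "baumann", n_patients = 100L,
                       visit = list(), prevalence = .default_prevalence,
                       severity_dist = .default_severity(),
                       extent_grade_dist = c(0.6, 0.3, 0.1),
                       lobe_involvement = 0.5,
                       observer = list(), drift_per_month = c(bronchiectasis = 0.02)) {
  visit_def <- list(counts = 1:9,
                    probs = c(57, 30, 16, 10, 7, 6, 5, 4, 3) / 138,
                    n_single = 0L, gap_meanlog = log(12), gap_sdlog = 1.03)
  visit <- utils::modifyList(visit_def, visit)
  observer_def <- list(n = 2L, confusion = 0.15, bias = c(0, 0), mm_sd = 2)
  observer <- utils::modifyList(observer_def, observer)

  cfg <- structure(
    list(seed = as.integer(seed), method = tolower(method),
         n_patients = as.integer(n_patients), visit = visit,
         prevalence = prevalence, severity_dist = severity_dist,
         extent_grade_dist = extent_grade_dist,
         lobe_involvement = lobe_involvement, observer = observer,
         drift_per_month = drift_per_month),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad_prob <- function(p) any(!is.finite(p)) || any(p < 0) || any(p > 1)
  problems <- character(0)
  if (!cfg$method %in% c("baumann", "hartmann")) {
    problems <- c(problems, paste0("unknown method '", cfg$method, "'"))
  }
  if (bad_prob(cfg$prevalence)) problems <- c(problems, "prevalence outside [0, 1]")
  if (bad_prob(cfg$lobe_involvement)) {
    problems <- c(problems, "lobe_involvement outside [0, 1]")
  }
  if (bad_prob(cfg$observer$confusion)) {
    problems <- c(problems, "observer confusion outside [0, 1]")
  }
  if (bad_prob(cfg$visit$probs) || abs(sum(cfg$visit$probs) - 1) > 1e-6) {
    problems <- c(problems, "visit count probabilities must sum to 1 within [0, 1]")
  }
  if (any(cfg$visit$counts < 1) || any(cfg$visit$counts > 9)) {
    problems <- c(problems, "scans per patient must lie in 1-9")
  }
  for (nm in names(cfg$severity_dist)) {
    d <- cfg$severity_dist[[nm]]
    if (bad_prob(d$probs) || abs(sum(d$probs) - 1) > 1e-6) {
      problems <- c(problems, paste0("severity distribution '", nm,
                                     "' probabilities must sum to 1"))
    }
  }
  if (length(problems)) {
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(cfg)
}

#' Study-like cohort preset
#'
#' A [sim_config()] emulating the shape of the reference GLILD cohort:
#' 138 patients of whom exactly 81 have two or more scans (drawn from 2-9),
#' median inter-scan gap about 12 months, high bronchiectasis and
#' GLILD-feature prevalences.
#'
#' @param seed Master seed.
#' @param method `"baumann"` or `"hartmann"`.
#' @return A `sim_config`.
#' @export
study_like_config <- function(seed = 1L, method = "baumann") {
  sim_config(
    seed = seed, method = method, n_patients = 138L,
    visit = list(n_single = 57L, counts = 2:9,
                 probs = c(0.38, 0.23, 0.14, 0.09, 0.06, 0.04, 0.03, 0.03),
                 gap_meanlog = log(12), gap_sdlog = 1.03))
}

# slot metadata used by the observer-noise model, computed once per schema
.slot_meta <- function(schema) {
  slots <- schema_slots(schema)
  idx <- match(slots$item_id, schema$items$item_id)
  list(slots = slots,
       kind = schema$items$value_kind[idx],
       allowed = schema$items$allowed_set[idx],
       range = schema$items$allowed_range[idx],
       key = ifelse(is.na(slots$lobe), slots$item_id,
                    paste(slots$item_id, slots$lobe, sep = ".")))
}

.sev_dist <- function(cfg, abn) {
  cfg$severity_dist[[abn]] %||% cfg$severity_dist$default
}

# latent disease state of one patient under one schema
.draw_patient_state <- function(cfg, schema) {
  abns <- .component_abnormalities(schema)
  state <- list()
  for (a in abns) {
    prev <- unname(cfg$prevalence[a])
    if (is.na(prev)) prev <- 0
    present <- runif(1) < prev
    if (!present) {
      state[[a]] <- list(present = FALSE)
      next
    }
    sd <- .sev_dist(cfg, a)
    sev <- sample(sd$grades, 1L, prob = sd$probs)
    lobes <- runif(6) < cfg$lobe_involvement
    if (!any(lobes)) lobes[sample.int(6, 1L)] <- TRUE
    ext_grades <- ifelse(lobes, sample(1:3, 6, replace = TRUE,
                                       prob = cfg$extent_grade_dist), 0)
    state[[a]] <- list(present = TRUE, severity = sev, lobes = lobes,
                       extent_grades = ext_grades)
  }
  ln_present <- runif(1) < (unname(cfg$prevalence["lymphadenopathy"]) %||% 0)
  if (is.na(ln_present)) ln_present <- FALSE
  state$.lymphadenopathy <- list(
    present = ln_present,
    mm = if (ln_present) 10 + rpois(1L, 4) else 0)
  state
}

# noise-free slot values at one visit time
.true_values <- function(cfg, schema, state, t) {
  vals <- c()
  drift <- cfg$drift_per_month
  for (a in .component_abnormalities(schema)) {
    st <- state[[a]]
    d <- unname(drift[a]); if (is.na(d) || is.null(d)) d <- 0
    if (schema$method_name == "baumann") {
      ext <- if (st$present) {
        min(6, max(0, round(sum(st$lobes) + d * t)))
      } else 0
      vals[paste0(a, "_extent")] <- ext
    } else {
      eg <- if (st$present) {
        pmin(3, pmax(0, round(st$extent_grades + ifelse(st$lobes, d * t, 0))))
      } else rep(0, 6)
      sev <- if (st$present) ifelse(eg > 0, st$severity, 0) else rep(0, 6)
      vals[paste0(a, "_extent.", schema$lobes)] <- eg
      vals[paste0(a, "_severity.", schema$lobes)] <- sev
    }
  }
  if (schema$method_name == "baumann") {
    sev_or_0 <- function(a) if (state[[a]]$present) state[[a]]$severity else 0
    vals["bronchiectasis_severity"] <- sev_or_0("bronchiectasis")
    vals["bronchial_wall_thickening_severity"] <-
      sev_or_0("bronchial_wall_thickening")
    vals["mucus_plugging_severity"] <-
      if (state$mucus_plugging$present) min(3, state$mucus_plugging$severity) else 0
    vals["nodule_size_category"] <- if (state$nodules$present)
      state$nodules$size_category else 0
    vals["reticulation_subtype"] <- if (state$reticulation$present)
      state$reticulation$subtype else 0
    vals["ggo_subtype"] <- if (state$ggo$present) state$ggo$subtype else 0
    vals["atelectasis_type"] <- if (state$atelectasis$present)
      state$atelectasis$subtype else 0
    vals["emphysema_bullae_type"] <- if (state$emphysema_bullae$present)
      state$emphysema_bullae$subtype else 0
    vals["lymph_node_mm"] <- state$.lymphadenopathy$mm
    # lymphadenopathy extent: number of "lobes" kept at 0/1 station-count proxy
    vals["lymphadenopathy_extent"] <-
      if (state$.lymphadenopathy$present) 1 else 0
  } else {
    vals["lymphadenopathy_presence"] <-
      as.numeric(state$.lymphadenopathy$present)
  }
  vals
}

# static per-patient qualifier draws used by the Baumann sheet
.draw_qualifiers <- function(cfg, state) {
  if (isTRUE(state$nodules$present)) {
    nd <- .sev_dist(cfg, "nodule_size")
    state$nodules$size_category <- sample(nd$grades, 1L, prob = nd$probs)
  }
  if (isTRUE(state$reticulation$present)) {
    state$reticulation$subtype <- sample(1:3, 1L)
  }
  if (isTRUE(state$ggo$present)) state$ggo$subtype <- sample(1:2, 1L)
  if (isTRUE(state$atelectasis$present)) {
    state$atelectasis$subtype <- sample(1:2, 1L)
  }
  if (isTRUE(state$emphysema_bullae$present)) {
    state$emphysema_bullae$subtype <- sample(1:2, 1L)
  }
  state
}

# adjacent-grade observer noise applied to a complete value vector
.observe_values <- function(vals, meta, confusion, bias, mm_sd) {
  out <- vals
  p_up <- min(0.95, max(0.05, 0.5 + bias))
  for (i in seq_along(meta$key)) {
    kind <- meta$kind[i]
    v <- out[meta$key[i]]
    if (kind == "measurement_mm") {
      if (mm_sd > 0) {
        rng <- meta$range[[i]]
        out[meta$key[i]] <- min(rng[["max"]],
                                max(rng[["min"]], round(v + rnorm(1, 0, mm_sd))))
      }
    } else if (kind == "presence") {
      if (runif(1) < confusion) out[meta$key[i]] <- 1 - v
    } else {
      if (confusion > 0 && runif(1) < confusion) {
        allowed <- meta$allowed[[i]]
        j <- which.min(abs(allowed - v))
        j <- j + if (runif(1) < p_up) 1L else -1L
        j <- min(length(allowed), max(1L, j))
        out[meta$key[i]] <- allowed[j]
      }
    }
  }
  out
}

#' Simulate a synthetic observer cohort
#'
#' Draws a cohort under `config` and emits complete, schema-valid score
#' sheets for each observer at each visit, together with the ground truth:
#' the noise-free sheets and (optionally) their component/composite percent
#' scores.  The same seed always yields an identical cohort.
#'
#' @param config A [sim_config()].
#' @param truth_scores If `TRUE` (default) the ground truth includes the
#'   percent score table of every noise-free sheet.
#' @return A `sim_cohort`: list with `sheets` (observer sheets),
#'   `truth` (list with `sheets`, `scores`, `drift_per_month`, `config`),
#'   and `schema`.
#' @examples
#' co <- simulate_cohort(sim_config(seed = 7, n_patients = 4))
#' length(co$sheets)
#' @export
simulate_cohort <- function(config, truth_scores = TRUE) {
  validate_sim_config(config)
  schema <- canonical_schema(config$method)
  meta <- .slot_meta(schema)
  n_obs <- config$observer$n
  bias <- rep_len(config$observer$bias, n_obs)

  sheets <- list()
  truth_sheets <- list()
  for (i in seq_len(config$n_patients)) {
    set.seed(.patient_seed(config$seed, i))
    pid <- sprintf("p%03d", i)

    n_scans <- if (i <= config$visit$n_single) 1L else
      sample(config$visit$counts, 1L, prob = config$visit$probs)
    gaps <- if (n_scans > 1L) {
      pmax(0.5, round(stats::rlnorm(n_scans - 1L, config$visit$gap_meanlog,
                                    config$visit$gap_sdlog), 1))
    } else numeric(0)
    times <- cumsum(c(0, gaps))

    state <- .draw_patient_state(config, schema)
    state <- .draw_qualifiers(config, state)

    for (v in seq_len(n_scans)) {
      sid <- sprintf("%s_s%d", pid, v)
      vals <- .true_values(config, schema, state, times[v])
      truth_sheets[[length(truth_sheets) + 1L]] <-
        sheet_from_values(schema, vals, patient_id = pid, scan_id = sid,
                          time_months = times[v], observer_id = "truth")
      for (o in seq_len(n_obs)) {
        ovals <- .observe_values(vals, meta, config$observer$confusion,
                                 bias[o], config$observer$mm_sd)
        sheets[[length(sheets) + 1L]] <-
          sheet_from_values(schema, ovals, patient_id = pid, scan_id = sid,
                            time_months = times[v],
                            observer_id = paste0("obs", o))
      }
    }
  }

  scores <- NULL
  if (isTRUE(truth_scores)) {
    scores <- do.call(rbind, lapply(truth_sheets, function(sh) {
      st <- score_table(sh, schema)
      data.frame(patient_id = sh$patient_id, scan_id = sh$scan_id,
                 time_months = sh$time_months, score_label = st$score_label,
                 percent = st$percent, stringsAsFactors = FALSE)
    }))
  }

  structure(
    list(sheets = sheets,
         truth = list(sheets = truth_sheets, scores = scores,
                      drift_per_month = config$drift_per_month,
                      config = config),
         schema = schema),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  n_pat <- length(unique(vapply(x$truth$sheets, `[[`, "", "patient_id")))
  cat(sprintf("<sim_cohort> %s method: %d patients, %d scans, %d observer sheets\n",
              x$schema$method_name, n_pat, length(x$truth$sheets),
              length(x$sheets)))
  invisible(x)
}

#' Monte-Carlo true ICC of an observer model
#'
#' Estimates the intraclass correlation implied by a simulation config for
#' one score by simulating a large single-visit cohort and computing
#' ICC(C,1) between the two observers.  With tens of thousands of subjects
#' the sampling error is negligible, so this serves as the ground-truth ICC
#' of the observer model.
#'
#' @param config A [sim_config()]; its visit model is overridden to a
#'   single scan per patient.
#' @param score_label Score to evaluate (component or composite label).
#' @param n_subjects Number of simulated subjects.
#' @return The Monte-Carlo ICC estimate (numeric).
#' @export
true_icc_mc <- function(config, score_label, n_subjects = 4000L) {
  cfg <- config
  cfg$n_patients <- as.integer(n_subjects)
  cfg$visit$counts <- 1L
  cfg$visit$probs <- 1
  cfg$visit$n_single <- 0L
  co <- simulate_cohort(cfg, truth_scores = FALSE)
  res <- agreement_study(co$sheets, co$schema, scores = score_label)
  res$estimate[1L]
}

#' Simulate continuous score trajectories
#'
#' Generates percent-score trajectories under the random-intercept linear
#' model `y = intercept + slope * t + b_patient + noise`, on a study-like
#' visit schedule (visits per patient from 2-9, log-normal gaps with a
#' 12-month median).  Used to calibrate and power the longitudinal engines
#' against a known slope.
#'
#' @param n_patients Number of patients (each with at least two visits).
#' @param slope True mean change per month.
#' @param intercept True mean at time zero.
#' @param sd_intercept SD of the patient-level random intercept.
#' @param sd_residual SD of the visit-level noise.
#' @param seed Seed.
#' @param visit Visit model as in [sim_config()] (counts restricted to
#'   at least 2).
#' @return A data frame with `patient_id`, `time_months`, `outcome` and
#'   attribute `true_slope`.
#' @export
simulate_score_trajectories <- function(n_patients = 81L, slope = 0.1,
                                        intercept = 20, sd_intercept = 8,
                                        sd_residual = 5, seed = 1L,
                                        visit = list()) {
  visit_def <- list(counts = 2:9,
                    probs = c(0.38, 0.23, 0.14, 0.09, 0.06, 0.04, 0.03, 0.03),
                    gap_meanlog = log(12), gap_sdlog = 1.03)
  visit <- utils::modifyList(visit_def, visit)
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    set.seed(.patient_seed(seed, i))
    n_v <- sample(visit$counts, 1L, prob = visit$probs)
    gaps <- pmax(0.5, round(stats::rlnorm(n_v - 1L, visit$gap_meanlog,
                                          visit$gap_sdlog), 1))
    t <- cumsum(c(0, gaps))
    b <- rnorm(1, 0, sd_intercept)
    y <- intercept + b + slope * t + rnorm(n_v, 0, sd_residual)
    rows[[i]] <- data.frame(patient_id = sprintf("p%03d", i),
                            time_months = t, outcome = y,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "true_slope") <- slope
  out
}
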