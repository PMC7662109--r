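# Test helpers: random valid sheets and independent re-implementations used
# as oracles.  The oracles deliberately share no code with the package: the
# multiplier tables are hard-coded and scores are accumulated slot by slot.

random_valid_sheet <- function(schema, patient_id = "p1", scan_id = "s1",
                               observer_id = "obs1", time_months = 0) {
  slots <- schema_slots(schema)
  items <- schema$items
  idx <- match(slots$item_id, items$item_id)
  vals <- vapply(seq_len(nrow(slots)), function(i) {
    set <- items$allowed_set[[idx[i]]]
    if (!is.null(set)) {
      sample(set, 1L)
    } else {
      rng <- items$allowed_range[[idx[i]]]
      sample(seq(rng[["min"]], min(rng[["max"]], 40)), 1L)
    }
  }, 0)
  score_sheet(patient_id, scan_id, time_months, observer_id,
              schema$method_name,
              data.frame(item_id = slots$item_id, lobe = slots$lobe,
                         value = vals, stringsAsFactors = FALSE))
}

# hard-coded multiplier lookups (grade 0 contributes nothing)
naive_mult <- function(abn, g) {
  tab <- if (abn == "bronchiectasis") {
    c("0" = 0, "1" = 1, "1.5" = 1.25, "2" = 1.5, "2.5" = 1.75, "3" = 2)
  } else {
    c("0" = 0, "1" = 1, "2" = 1.25, "3" = 1.5)
  }
  unname(tab[as.character(g)])
}

# slot-by-slot re-computation of a component percent, written independently
naive_component_percent <- function(sheet, abn, method) {
  v <- sheet$values
  get1 <- function(item) v$value[v$item_id == item & is.na(v$lobe)]
  getl <- function(item, lobe) v$value[v$item_id == item & !is.na(v$lobe) &
                                         v$lobe == lobe]
  lobes <- c("RUL", "RML", "RLL", "LUL", "lingula", "LLL")
  weighted <- abn %in% c("bronchiectasis", "bronchial_wall_thickening")
  top <- if (abn == "bronchiectasis") 2 else 1.5
  if (method == "baumann") {
    ext <- get1(paste0(abn, "_extent"))
    if (weighted) {
      raw <- ext * naive_mult(abn, get1(paste0(abn, "_severity")))
      mx <- 6 * top
    } else {
      raw <- ext
      mx <- 6
    }
  } else {
    raw <- 0
    for (lb in lobes) {
      e <- getl(paste0(abn, "_extent"), lb)
      if (weighted) {
        raw <- raw + e * naive_mult(abn, getl(paste0(abn, "_severity"), lb))
      } else {
        raw <- raw + e
      }
    }
    mx <- if (weighted) 18 * top else 18
  }
  100 * raw / mx
}

naive_composite_percent <- function(sheet, name, method,
                                    exclusions = "trapped_air") {
  members <- switch(name,
    glild = c("ggo", "nodules", "reticulation"),
    airway = c("bronchial_wall_thickening", "bronchiectasis",
               "mucus_plugging"),
    total = if (method == "baumann") {
      c("bronchial_wall_thickening", "bronchiectasis", "mucus_plugging",
        "atelectasis", "nodules", "reticulation", "consolidation", "ggo",
        "cysts", "emphysema_bullae", "scars_bands", "trapped_air",
        "lymphadenopathy")
    } else {
      c("bronchial_wall_thickening", "bronchiectasis", "mucus_plugging",
        "atelectasis", "nodules", "reticulation", "consolidation", "ggo",
        "bullae", "cysts", "emphysema", "distortion", "trapped_air")
    })
  members <- setdiff(members, exclusions)
  raw <- 0; mx <- 0
  for (abn in members) {
    p <- naive_component_percent(sheet, abn, method)
    weighted <- abn %in% c("bronchiectasis", "bronchial_wall_thickening")
    top <- if (abn == "bronchiectasis") 2 else 1.5
    m_abn <- if (method == "baumann") {
      if (weighted) 6 * top else 6
    } else {
      if (weighted) 18 * top else 18
    }
    raw <- raw + p * m_abn / 100
    mx <- mx + m_abn
  }
  100 * raw / mx
}

# textbook two-way ANOVA consistency ICC via stats::aov mean squares
aov_icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse)
}

zero_noise_config <- function(seed = 1, method = "baumann", n_patients = 10,
                              ...) {
  sim_config(seed = seed, method = method, n_patients = n_patients,
             observer = list(confusion = 0, bias = c(0, 0), mm_sd = 0), ...)
}
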