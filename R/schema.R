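#' @importFrom stats median quantile setNames var aggregate pchisq pnorm rbinom
#'   rnorm runif rpois sd lm coef vcov logLik resid as.formula predict anova
#' @importFrom utils read.csv write.csv packageVersion head
NULL

# Canonical lobe model shared by both methods: five anatomical lobes plus the
# lingula treated as a sixth, separate lobe.
CANONICAL_LOBES <- c("RUL", "RML", "RLL", "LUL", "lingula", "LLL")

VALID_SCOPES <- c("per_lobe", "whole_lung", "once")
VALID_VALUE_KINDS <- c(
  "extent_lobe_count", "extent_grade", "severity_grade", "size_category",
  "measurement_mm", "presence", "subtype_category"
)

.schema_cache <- new.env(parent = emptyenv())

#' Built-in canonical scoring schema
#'
#' Returns the package's built-in schema for one of the two CVID chest-CT
#' scoring methods.  The Baumann method scores 13 abnormalities for the whole
#' lung (extent as number of affected lobes, 0-6) plus severity grades,
#' qualifiers and a lymph-node measurement: 22 values per CT.  The Hartmann
#' method scores 13 abnormalities per lobe (extent and severity, each 0-3;
#' six lobes with the lingula counted separately) plus a single
#' lymphadenopathy presence item: 26 x 6 + 1 = 157 values per CT.
#'
#' @param method_name `"baumann"` or `"hartmann"` (case-insensitive).
#' @return A `scoring_schema` object.
#' @seealso [load_schema()] for reading schema documents from file.
#' @examples
#' canonical_schema("baumann")$value_slot_count   # 22
#' canonical_schema("hartmann")$value_slot_count  # 157
#' @export
canonical_schema <- function(method_name) {
  stopifnot(is.character(method_name), length(method_name) == 1L)
  method <- tolower(method_name)
  if (!method %in% c("baumann", "hartmann")) {
    stop("unsupported scoring method: '", method_name,
         "' (supported: baumann, hartmann)", call. = FALSE)
  }
  if (!is.null(.schema_cache[[method]])) return(.schema_cache[[method]])
  path <- system.file("extdata", "schemas", paste0(method, "_default.yaml"),
                      package = "glildscore", mustWork = TRUE)
  schema <- load_schema(path)
  .schema_cache[[method]] <- schema
  schema
}

#' Load and validate a scoring schema document
#'
#' Reads a schema from a YAML or JSON document (or an already-parsed list)
#' and checks every structural invariant: six canonical lobes, unique item
#' identifiers, known scopes and value kinds, non-empty allowed-value sets.
#' The total number of value slots is always computed from the items (one
#' slot per whole-lung/once item, six per per-lobe item), never read from
#' the document.
#'
#' Documents may declare per-lobe (extent, severity) item pairs compactly
#' through an `abnormalities` block; the loader expands each entry into
#' `<name>_extent` (grades 0-3) and `<name>_severity` items.
#'
#' @param x Path to a `.yaml`/`.yml`/`.json` file, or a list with the parsed
#'   document.
#' @return A `scoring_schema`: a list with `method_name`, `lobes`, `items`
#'   (a data frame with one row per item), `multipliers`, and the computed
#'   `value_slot_count`.
#' @export
load_schema <- function(x) {
  doc <- if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.json$", x, ignore.case = TRUE)) {
      jsonlite::read_json(x, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(x)
    }
  } else if (is.list(x)) {
    x
  } else {
    stop("load_schema() expects a file path or a parsed list", call. = FALSE)
  }

  problems <- character(0)
  method <- tolower(as.character(doc$method_name %||% ""))
  if (!nzchar(method)) problems <- c(problems, "missing method_name")

  lobes <- as.character(unlist(doc$lobes))
  if (length(lobes) != 6L) {
    problems <- c(problems, sprintf(
      "schema must declare exactly 6 lobes (got %d); the lingula is a separate lobe",
      length(lobes)))
  } else if (!identical(tolower(lobes), tolower(CANONICAL_LOBES))) {
    problems <- c(problems, paste0(
      "lobes must be, in order: ", paste(CANONICAL_LOBES, collapse = ", ")))
  }

  items <- lapply(doc$items %||% list(), .normalise_item)
  # expand the compact per-lobe abnormality block into extent/severity pairs
  for (abn in doc$abnormalities %||% list()) {
    nm <- tolower(as.character(abn$name))
    comp <- as.character(unlist(abn$composites))
    excl <- isTRUE(abn$excludable)
    items <- c(items, list(
      .normalise_item(list(
        item_id = paste0(nm, "_extent"), abnormality = nm, scope = "per_lobe",
        value_kind = "extent_grade", allowed = list(set = c(0, 1, 2, 3)),
        composites = comp, excludable = excl)),
      .normalise_item(list(
        item_id = paste0(nm, "_severity"), abnormality = nm, scope = "per_lobe",
        value_kind = "severity_grade",
        allowed = list(set = as.numeric(unlist(abn$severity_allowed))),
        composites = character(0), excludable = excl))
    ))
  }

  if (length(items) == 0L) problems <- c(problems, "schema declares no items")
  ids <- vapply(items, `[[`, "", "item_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate item_id: ", paste(dup, collapse = ", ")))
  }
  for (it in items) {
    if (!it$scope %in% VALID_SCOPES) {
      problems <- c(problems, sprintf("item '%s': unknown scope '%s'", it$item_id, it$scope))
    }
    if (!it$value_kind %in% VALID_VALUE_KINDS) {
      problems <- c(problems, sprintf("item '%s': unknown value_kind '%s'",
                                      it$item_id, it$value_kind))
    }
    if (is.null(it$allowed_set) && is.null(it$allowed_range)) {
      problems <- c(problems, sprintf("item '%s': empty allowed_values", it$item_id))
    }
    # traction bronchiectasis is explicitly out of both methods' definitions
    if (grepl("traction_bronchiectasis", it$item_id) ||
        identical(it$abnormality, "traction_bronchiectasis")) {
      problems <- c(problems, sprintf(
        "item '%s': traction bronchiectasis is excluded from bronchiectasis scoring by definition",
        it$item_id))
    }
  }
  if (length(problems)) {
    stop("invalid schema document:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }

  items_df <- data.frame(
    item_id = ids,
    abnormality = vapply(items, `[[`, "", "abnormality"),
    scope = vapply(items, `[[`, "", "scope"),
    value_kind = vapply(items, `[[`, "", "value_kind"),
    excludable = vapply(items, function(i) isTRUE(i$excludable), NA),
    reconstructed = vapply(items, function(i) isTRUE(i$reconstructed), NA),
    stringsAsFactors = FALSE
  )
  items_df$allowed_set <- lapply(items, `[[`, "allowed_set")
  items_df$allowed_range <- lapply(items, `[[`, "allowed_range")
  items_df$composites <- lapply(items, `[[`, "composites")

  multipliers <- lapply(doc$multipliers %||% list(), function(m) {
    grades <- as.numeric(names(m))
    setNames(as.numeric(unlist(m)), grades)
  })
  names(multipliers) <- tolower(names(doc$multipliers %||% list()))
  for (nm in names(multipliers)) {
    m <- multipliers[[nm]]
    m <- m[order(as.numeric(names(m)))]
    if (any(diff(m) <= 0)) {
      stop("multiplier table for '", nm, "' must be strictly increasing in grade",
           call. = FALSE)
    }
    if (abs(m[[1L]] - 1) > 1e-12) {
      stop("multiplier of the lowest nonzero grade of '", nm, "' must be 1.00",
           call. = FALSE)
    }
    multipliers[[nm]] <- m
  }

  n_slots <- sum(ifelse(items_df$scope == "per_lobe", 6L, 1L))
  structure(
    list(method_name = method, lobes = CANONICAL_LOBES, items = items_df,
         multipliers = multipliers, value_slot_count = n_slots),
    class = "scoring_schema"
  )
}

.normalise_item <- function(it) {
  allowed <- it$allowed %||% list()
  set <- if (!is.null(allowed$set)) as.numeric(unlist(allowed$set)) else NULL
  rng <- if (!is.null(allowed$min) || !is.null(allowed$max)) {
    c(min = as.numeric(allowed$min %||% 0), max = as.numeric(allowed$max %||% Inf))
  } else NULL
  if (!is.null(set) && length(set) == 0L) set <- NULL
  list(
    item_id = tolower(as.character(it$item_id %||% "")),
    abnormality = tolower(as.character(it$abnormality %||% "")),
    scope = tolower(as.character(it$scope %||% "")),
    value_kind = tolower(as.character(it$value_kind %||% "")),
    allowed_set = set,
    allowed_range = rng,
    composites = tolower(as.character(unlist(it$composites))),
    excludable = isTRUE(it$excludable),
    reconstructed = isTRUE(it$reconstructed)
  )
}

#' Serialise a scoring schema back to a document list
#'
#' Inverse of [load_schema()] up to the compact `abnormalities` shorthand:
#' the result always uses the explicit `items` form. Useful for writing a
#' modified schema to YAML/JSON.
#'
#' @param schema A `scoring_schema`.
#' @return A plain list suitable for `yaml::write_yaml()` or
#'   `jsonlite::write_json()`.
#' @export
schema_to_document <- function(schema) {
  stopifnot(inherits(schema, "scoring_schema"))
  items <- lapply(seq_len(nrow(schema$items)), function(i) {
    row <- schema$items[i, ]
    allowed <- if (!is.null(row$allowed_set[[1L]])) {
      list(set = row$allowed_set[[1L]])
    } else {
      as.list(row$allowed_range[[1L]])
    }
    out <- list(item_id = row$item_id, abnormality = row$abnormality,
                scope = row$scope, value_kind = row$value_kind,
                allowed = allowed, composites = as.list(row$composites[[1L]]))
    if (row$excludable) out$excludable <- TRUE
    if (row$reconstructed) out$reconstructed <- TRUE
    out
  })
  mult <- lapply(schema$multipliers, function(m) as.list(setNames(unname(m), names(m))))
  list(method_name = schema$method_name, lobes = as.list(schema$lobes),
       multipliers = mult, items = items)
}

#' Expanded slot list of a schema
#'
#' One row per scored value: per-lobe items appear once per lobe, whole-lung
#' and once items appear once with `lobe = NA`.
#'
#' @param schema A `scoring_schema`.
#' @return Data frame with columns `item_id`, `lobe`.
#' @export
schema_slots <- function(schema) {
  stopifnot(inherits(schema, "scoring_schema"))
  per_lobe <- schema$items$scope == "per_lobe"
  slots <- rbind(
    if (any(per_lobe)) data.frame(
      item_id = rep(schema$items$item_id[per_lobe], each = length(schema$lobes)),
      lobe = rep(schema$lobes, sum(per_lobe)), stringsAsFactors = FALSE),
    if (any(!per_lobe)) data.frame(
      item_id = schema$items$item_id[!per_lobe], lobe = NA_character_,
      stringsAsFactors = FALSE)
  )
  rownames(slots) <- NULL
  slots
}

#' Validate a score sheet against a schema
#'
#' Checks that every slot required by the schema is present exactly once,
#' that no extra slots exist, that every value lies in its item's allowed
#' set/range, and that `time_months` is nonnegative.  Validation is total:
#' it never raises on any finite input, it returns the violations.
#'
#' @param sheet A `score_sheet` (see [score_sheet()]).
#' @param schema A `scoring_schema`.
#' @return A data frame with columns `item_id`, `lobe`, `value`, `rule`;
#'   zero rows when the sheet is valid.
#' @export
validate_sheet <- function(sheet, schema) {
  stopifnot(inherits(sheet, "score_sheet"), inherits(schema, "scoring_schema"))
  v <- sheet$values
  viol <- list()
  add <- function(item, lobe, value, rule) {
    viol[[length(viol) + 1L]] <<- data.frame(
      item_id = item, lobe = lobe, value = value, rule = rule,
      stringsAsFactors = FALSE)
  }

  if (!identical(tolower(sheet$method_name), schema$method_name)) {
    add(NA_character_, NA_character_, NA_real_,
        sprintf("method mismatch: sheet '%s' vs schema '%s'",
                sheet$method_name, schema$method_name))
  }
  if (!is.finite(sheet$time_months) || sheet$time_months < 0) {
    add(NA_character_, NA_character_, sheet$time_months,
        "time_months must be a nonnegative number")
  }

  slots <- schema_slots(schema)
  want <- paste(slots$item_id, ifelse(is.na(slots$lobe), "", tolower(slots$lobe)))
  have <- paste(tolower(v$item_id), ifelse(is.na(v$lobe), "", tolower(v$lobe)))

  missing <- !(want %in% have)
  for (i in which(missing)) {
    add(slots$item_id[i], slots$lobe[i], NA_real_, "required slot missing")
  }
  extra <- !(have %in% want)
  for (i in which(extra)) {
    add(v$item_id[i], v$lobe[i], v$value[i], "slot not defined by schema")
  }
  dup <- duplicated(have)
  for (i in which(dup & !extra)) {
    add(v$item_id[i], v$lobe[i], v$value[i], "slot present more than once")
  }

  idx <- match(tolower(v$item_id), schema$items$item_id)
  for (i in which(!extra & !dup)) {
    j <- idx[i]
    if (is.na(j)) next
    val <- v$value[i]
    set <- schema$items$allowed_set[[j]]
    rng <- schema$items$allowed_range[[j]]
    ok <- if (!is.null(set)) {
      is.finite(val) && any(abs(set - val) < 1e-9)
    } else {
      is.finite(val) && val >= rng[["min"]] && val <= rng[["max"]]
    }
    if (!ok) {
      allowed_txt <- if (!is.null(set)) paste(set, collapse = ",") else
        paste0("[", rng[["min"]], ", ", rng[["max"]], "]")
      add(v$item_id[i], v$lobe[i], val,
          paste0("value outside allowed set {", allowed_txt, "}"))
    }
  }

  if (length(viol) == 0L) {
    return(data.frame(item_id = character(0), lobe = character(0),
                      value = numeric(0), rule = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}

#' @export
print.scoring_schema <- function(x, ...) {
  cat(sprintf("<scoring_schema> %s method\n", x$method_name))
  cat(sprintf("  lobes: %s\n", paste(x$lobes, collapse = ", ")))
  cat(sprintf("  items: %d (%d per-lobe, %d whole-lung, %d once)\n",
              nrow(x$items), sum(x$items$scope == "per_lobe"),
              sum(x$items$scope == "whole_lung"), sum(x$items$scope == "once")))
  cat(sprintf("  value slots per CT: %d\n", x$value_slot_count))
  if (any(x$items$reconstructed)) {
    cat("  reconstructed placeholder items: ",
        paste(x$items$item_id[x$items$reconstructed], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
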