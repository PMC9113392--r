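#' Age bands used throughout the package
#'
#' Visits are banded into the seven age groups used in pediatric emergency
#' triage reporting: 0--28 days (newborn), 28 days--3 months, 3 months--1
#' year, 1--3, 3--7, 7--12 and 12--18 years. Bands are half-open on the
#' right, with one month = 30.44 days and one year = 365.25 days.
#'
#' @format A character vector of band labels, in increasing age order.
#' @export
AGE_BANDS <- c("0-28d", "28d-3m", "3m-1y", "1-3y", "3-7y", "7-12y", "12-18y")

DAYS_PER_MONTH <- 30.44
DAYS_PER_YEAR <- 365.25

age_band_breaks <- function() {
  c(0, 28, 3 * DAYS_PER_MONTH, DAYS_PER_YEAR,
    3 * DAYS_PER_YEAR, 7 * DAYS_PER_YEAR, 12 * DAYS_PER_YEAR,
    18 * DAYS_PER_YEAR)
}

#' Assign an age in days to its age band
#'
#' @param age_days Non-negative integer vector of ages in days.
#' @return A factor with levels [AGE_BANDS]; ages of 18 years or more are
#'   `NA` (outside the pediatric population).
#' @export
#' @examples
#' age_band(c(0, 27, 28, 400))
age_band <- function(age_days) {
  stopifnot(is.numeric(age_days), all(age_days >= 0, na.rm = TRUE))
  cut(age_days, breaks = age_band_breaks(), labels = AGE_BANDS,
      right = FALSE, include.lowest = FALSE)
}

#' Complaint categories of the default item table
#'
#' Medical and surgical chief-complaint categories used by the default
#' synthetic item table and by the complaint stratifier.
#'
#' @format Named list with elements `medical` and `surgical`, each a
#'   character vector of category labels.
#' @export
COMPLAINT_CATEGORIES <- list(
  medical = c("ent", "pulmonary", "cardiovascular", "neurology",
              "digestive", "urology_nephrology", "gynecology",
              "dermatology", "endocrinology_metabolism", "infectious",
              "rheumatology_pain", "hematology", "poisoning",
              "other_medical"),
  surgical = c("head_neck_trauma", "upper_limb_trauma", "lower_limb_trauma",
               "trunk_pelvis_urogenital_trauma", "burns", "other_surgical")
)

#' Map a complaint category to its complaint type
#'
#' @param category Character vector of category labels.
#' @return Character vector, `"medical"` or `"surgical"`.
#' @export
complaint_type <- function(category) {
  out <- ifelse(category %in% COMPLAINT_CATEGORIES$medical, "medical",
                ifelse(category %in% COMPLAINT_CATEGORIES$surgical,
                       "surgical", NA_character_))
  if (anyNA(out)) {
    ped_stop("pedtriage_unknown_category",
             paste0("unknown complaint category: ",
                    paste(unique(category[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Construct a triage item table
#'
#' An item table maps chief-complaint item labels to a complaint category
#' and a base triage level (1 = most severe ... 5 = least severe). Item
#' labels must be unique; lookups of undeclared labels are errors.
#'
#' @param items A data frame with columns `label` (character, unique,
#'   non-empty), `category` (a label from [COMPLAINT_CATEGORIES]) and
#'   `base_level` (integer 1--5).
#' @param version Character version string recorded in the table.
#' @return An object of class `item_table`.
#' @export
item_table <- function(items, version = "unversioned") {
  stopifnot(is.data.frame(items),
            all(c("label", "category", "base_level") %in% names(items)))
  items$label <- as.character(items$label)
  items$category <- as.character(items$category)
  items$base_level <- as.integer(items$base_level)
  if (any(!nzchar(items$label)) || anyNA(items$label)) {
    ped_stop("pedtriage_bad_item", "item labels must be non-empty")
  }
  if (anyDuplicated(items$label)) {
    ped_stop("pedtriage_bad_item",
             paste0("duplicate item labels: ",
                    paste(unique(items$label[duplicated(items$label)]),
                          collapse = ", ")))
  }
  if (!all(items$base_level %in% 1:5)) {
    ped_stop("pedtriage_bad_item", "base_level must be in 1..5")
  }
  complaint_type(items$category)  # validates categories
  structure(list(items = items, version = as.character(version)),
            class = "item_table")
}

#' @export
print.item_table <- function(x, ...) {
  cat("<item_table> version ", x$version, ": ", nrow(x$items),
      " items across ", length(unique(x$items$category)),
      " categories\n", sep = "")
  invisible(x)
}

#' Look up items in an item table
#'
#' @param table An [item_table()].
#' @param labels Character vector of item labels.
#' @return The matching rows of the item data frame, in `labels` order.
#' @export
lookup_items <- function(table, labels) {
  stopifnot(inherits(table, "item_table"))
  idx <- match(labels, table$items$label)
  if (anyNA(idx)) {
    ped_stop("pedtriage_unknown_item",
             paste0("unknown item label(s): ",
                    paste(labels[is.na(idx)], collapse = ", ")),
             labels = labels[is.na(idx)])
  }
  table$items[idx, , drop = FALSE]
}

#' Construct a risk-condition table
#'
#' Risk conditions (e.g. newborn, immunosuppressed) force a visit to at
#' most the configured triage level. A condition with `age_max_days` set is
#' age-derived and matched automatically from the visit's age, whether or
#' not the nurse flagged it.
#'
#' @param conditions Data frame with columns `label`, `assigned_level`
#'   (integer 1--5) and optionally `age_max_days` (numeric, `NA` when the
#'   condition is not age-derived).
#' @return Validated data frame of class `risk_conditions`.
#' @export
risk_conditions <- function(conditions) {
  stopifnot(is.data.frame(conditions),
            all(c("label", "assigned_level") %in% names(conditions)))
  conditions$label <- as.character(conditions$label)
  conditions$assigned_level <- as.integer(conditions$assigned_level)
  if (is.null(conditions$age_max_days)) conditions$age_max_days <- NA_real_
  if (!all(conditions$assigned_level %in% 1:5)) {
    ped_stop("pedtriage_bad_risk_condition", "assigned_level must be in 1..5")
  }
  if (anyDuplicated(conditions$label)) {
    ped_stop("pedtriage_bad_risk_condition", "duplicate risk-condition labels")
  }
  class(conditions) <- c("risk_conditions", "data.frame")
  conditions
}

#' Construct an age-banded vital-sign reference-range table
#'
#' One row per (age band x vital sign): values strictly below `min` or
#' strictly above `max` are out of range and escalate the triage level to
#' at most `escalation_level`. `NA` bounds are unbounded on that side. The
#' vital `oxygen_support` is conventionally given `max = 0`, so any oxygen
#' flow above 0 L/min escalates.
#'
#' @param ranges Data frame with columns `band` (an [AGE_BANDS] label),
#'   `vital` (one of glasgow, heart_rate, resp_rate, spo2,
#'   oxygen_support), `min`, `max`, `escalation_level` (integer 1--5).
#' @return Validated data frame of class `vital_ranges`.
#' @export
vital_ranges <- function(ranges) {
  stopifnot(is.data.frame(ranges),
            all(c("band", "vital", "min", "max", "escalation_level")
                %in% names(ranges)))
  if (!all(ranges$band %in% AGE_BANDS)) {
    ped_stop("pedtriage_bad_range", "band labels must be AGE_BANDS labels")
  }
  vitals <- c("glasgow", "heart_rate", "resp_rate", "spo2", "oxygen_support")
  if (!all(ranges$vital %in% vitals)) {
    ped_stop("pedtriage_bad_range",
             paste0("vital must be one of: ", paste(vitals, collapse = ", ")))
  }
  if (!all(ranges$escalation_level %in% 1:5)) {
    ped_stop("pedtriage_bad_range", "escalation_level must be in 1..5")
  }
  ranges$escalation_level <- as.integer(ranges$escalation_level)
  class(ranges) <- c("vital_ranges", "data.frame")
  ranges
}

#' Bundle a full triage configuration
#'
#' @param items An [item_table()].
#' @param risks A [risk_conditions()] table.
#' @param ranges A [vital_ranges()] table.
#' @param version Version string of the bundle.
#' @return An object of class `triage_config`.
#' @export
triage_config <- function(items, risks, ranges, version = "unversioned") {
  stopifnot(inherits(items, "item_table"),
            inherits(risks, "risk_conditions"),
            inherits(ranges, "vital_ranges"))
  structure(list(items = items, risk_conditions = risks,
                 vital_ranges = ranges, version = as.character(version)),
            class = "triage_config")
}

#' @export
print.triage_config <- function(x, ...) {
  cat("<triage_config> version ", x$version, "\n", sep = "")
  cat("  items: ", nrow(x$items$items), "\n", sep = "")
  cat("  risk conditions: ",
      paste(x$risk_conditions$label, collapse = ", "), "\n", sep = "")
  cat("  vital ranges: ", nrow(x$vital_ranges), " rows over ",
      length(unique(x$vital_ranges$band)), " age bands\n", sep = "")
  invisible(x)
}

#' Default synthetic triage configuration
#'
#' The clinical content of real five-level triage tools is proprietary and
#' unpublished, so the default configuration is deliberately synthetic: a
#' complete grid of one item per (complaint category x level) named
#' `"<category>/L<level>"`, a handful of human-readable aliases (e.g.
#' `"respiratory distress"` at level 2), newborn and immunosuppressed risk
#' conditions at level 2, and plausible age-banded pediatric vital-sign
#' ranges, every out-of-range escalation targeting level 2. It exercises
#' the full rule semantics but makes no claim to clinical fidelity.
#'
#' @return A [triage_config()].
#' @export
default_triage_config <- function() {
  cats <- unlist(COMPLAINT_CATEGORIES, use.names = FALSE)
  grid <- expand.grid(category = cats, base_level = 1:5,
                      stringsAsFactors = FALSE)
  grid$label <- sprintf("%s/L%d", grid$category, grid$base_level)
  named <- data.frame(
    label = c("respiratory distress", "fever", "vomiting",
              "limb trauma, deformity", "limb trauma, no deformity",
              "rash, well child"),
    category = c("pulmonary", "infectious", "digestive",
                 "upper_limb_trauma", "upper_limb_trauma", "dermatology"),
    base_level = c(2L, 3L, 3L, 3L, 4L, 5L),
    stringsAsFactors = FALSE)
  items <- item_table(rbind(grid[c("label", "category", "base_level")], named),
                      version = "synthetic-1.0")

  risks <- risk_conditions(data.frame(
    label = c("newborn", "immunosuppressed"),
    assigned_level = c(2L, 2L),
    age_max_days = c(28, NA),
    stringsAsFactors = FALSE))

  # plausible pediatric reference ranges; synthetic, escalation to level 2
  hr <- list(c(100, 180), c(100, 180), c(90, 160), c(80, 150),
             c(70, 130), c(60, 120), c(50, 110))
  rr <- list(c(30, 60), c(30, 60), c(25, 50), c(20, 40),
             c(18, 30), c(14, 26), c(12, 22))
  rows <- do.call(rbind, lapply(seq_along(AGE_BANDS), function(i) {
    data.frame(
      band = AGE_BANDS[i],
      vital = c("heart_rate", "resp_rate", "spo2", "glasgow",
                "oxygen_support"),
      min = c(hr[[i]][1], rr[[i]][1], 94, 14, NA),
      max = c(hr[[i]][2], rr[[i]][2], NA, NA, 0),
      escalation_level = 2L,
      stringsAsFactors = FALSE)
  }))
  ranges <- vital_ranges(rows)

  triage_config(items, risks, ranges, version = "synthetic-1.0")
}

#' Read a triage configuration from YAML or JSON
#'
#' The file must contain a `version` string and three blocks: `items`
#' (list of label/category/base_level records), `risk_conditions` and
#' `vital_ranges`, mirroring the in-memory tables.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [triage_config()].
#' @seealso [write_triage_config()]
#' @export
read_triage_config <- function(path) {
  raw <- read_config_file(path)
  needed <- c("items", "risk_conditions", "vital_ranges")
  if (!all(needed %in% names(raw))) {
    ped_stop("pedtriage_bad_config",
             paste0("config must contain blocks: ",
                    paste(needed, collapse = ", ")))
  }
  to_df <- function(recs) {
    merge_records(lapply(recs, function(r) {
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
    }))
  }
  risks <- to_df(raw$risk_conditions)
  if (is.null(risks$age_max_days)) risks$age_max_days <- NA_real_
  ranges <- to_df(raw$vital_ranges)
  for (col in c("min", "max")) {
    if (is.null(ranges[[col]])) ranges[[col]] <- NA_real_
    ranges[[col]] <- as.numeric(ranges[[col]])
  }
  triage_config(item_table(to_df(raw$items),
                           version = raw$version %||% "unversioned"),
                risk_conditions(risks),
                vital_ranges(ranges),
                version = raw$version %||% "unversioned")
}

#' Write a triage configuration to YAML or JSON
#'
#' @param config A [triage_config()].
#' @param path Destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_triage_config <- function(config, path) {
  stopifnot(inherits(config, "triage_config"))
  df_recs <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      rec <- as.list(df[i, , drop = FALSE])
      rec <- lapply(rec, function(v) if (is.na(v)) NULL else v)
      rec[!vapply(rec, is.null, logical(1))]
    })
  }
  out <- list(version = config$version,
              items = df_recs(config$items$items),
              risk_conditions = df_recs(as.data.frame(config$risk_conditions)),
              vital_ranges = df_recs(as.data.frame(config$vital_ranges)))
  write_config_file(out, path)
  invisible(path)
}

read_config_file <- function(path) {
  if (!file.exists(path)) {
    ped_stop("pedtriage_io_error", paste0("file not found: ", path))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

write_config_file <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
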