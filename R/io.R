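VISIT_SCHEMA <- "pedtriage-visit-table"
VISIT_SCHEMA_VERSION <- 1L

VISIT_COLUMNS <- c("visit_id", "age_days", "sex", "critical_flag", "items",
                   "risk_conditions", "glasgow", "heart_rate", "resp_rate",
                   "spo2", "oxygen_support", "pews_behavior",
                   "pews_cardiovascular", "pews_respiratory", "outcome",
                   "los_minutes")

EXCLUSION_FLAGS <- c("psychiatric", "left_without_being_seen",
                     "unreliable_vitals")

# declared types of the standard columns, applied after reading so that
# all-absent columns keep their type across round trips
VISIT_COLUMN_TYPES <- c(
  visit_id = "character", age_days = "integer", sex = "character",
  critical_flag = "logical", items = "character",
  risk_conditions = "character", glasgow = "numeric",
  heart_rate = "numeric", resp_rate = "numeric", spo2 = "numeric",
  oxygen_support = "numeric", pews_behavior = "integer",
  pews_cardiovascular = "integer", pews_respiratory = "integer",
  outcome = "character", los_minutes = "numeric", age_band = "character",
  complaint_category = "character", complaint_type = "character",
  diagnosis = "character", intended_level = "integer",
  intended_acuity = "character", suggested_level = "integer",
  final_level = "integer", fractile_minutes = "integer",
  psychiatric = "logical", left_without_being_seen = "logical",
  unreliable_vitals = "logical")

coerce_visit_types <- function(visits) {
  for (col in intersect(names(visits), names(VISIT_COLUMN_TYPES))) {
    visits[[col]] <- switch(VISIT_COLUMN_TYPES[[col]],
                            character = as.character(visits[[col]]),
                            integer = as.integer(visits[[col]]),
                            numeric = as.numeric(visits[[col]]),
                            logical = as.logical(visits[[col]]))
  }
  visits
}

#' Read a visit table
#'
#' Reads visits from CSV (header row mandatory, `#`-prefixed schema
#' header line, empty string = absent value) or JSON-lines (a schema
#' header object on the first line, then one visit object per line).
#' When `apply_exclusions = TRUE` the standard diagnostic-study exclusion
#' filters are applied — psychiatric visits, patients who left without
#' being seen, visits whose vital signs were flagged unreliable, and
#' visits with no recorded outcome — and a STARD-style disposition count
#' of each reason is returned alongside the included visits.
#'
#' @param path Input file.
#' @param dialect `"auto"` (from the extension), `"csv"` or `"jsonl"`.
#' @param apply_exclusions Apply the named exclusion filters?
#' @return List with `visits` (data frame) and `disposition` (named
#'   counts: rows read, each exclusion reason, included).
#' @export
read_visits <- function(path, dialect = c("auto", "csv", "jsonl"),
                        apply_exclusions = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
               else "csv"
  }
  if (!file.exists(path)) {
    ped_stop("pedtriage_io_error", paste0("file not found: ", path))
  }
  if (dialect == "csv") {
    first <- readLines(path, n = 1L)
    if (!startsWith(first, paste0("# ", VISIT_SCHEMA))) {
      ped_stop("pedtriage_schema",
               paste0("missing schema header line '# ", VISIT_SCHEMA,
                      " v", VISIT_SCHEMA_VERSION, "'"))
    }
    visits <- utils::read.csv(path, comment.char = "#", na.strings = "",
                              stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    if (length(lines) == 0L) {
      ped_stop("pedtriage_schema", "empty JSON-lines file")
    }
    header <- jsonlite::fromJSON(lines[1])
    if (!identical(header$schema, VISIT_SCHEMA)) {
      ped_stop("pedtriage_schema", "first JSON-lines record must declare the schema")
    }
    recs <- lapply(lines[-1], function(l) {
      r <- jsonlite::fromJSON(l)
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
    })
    visits <- if (length(recs)) merge_records(recs) else
      stats::setNames(data.frame(matrix(ncol = length(VISIT_COLUMNS),
                                        nrow = 0)), VISIT_COLUMNS)
    declared <- unlist(header$columns)
    if (length(declared) > 0L && nrow(visits) > 0L) {
      for (m in setdiff(declared, names(visits))) visits[[m]] <- NA
      visits <- visits[declared]
    }
  }
  visits <- coerce_visit_types(visits)
  validate_visit_table(visits)
  total <- nrow(visits)
  disposition <- c(rows_read = total)
  if (apply_exclusions) {
    for (flag in EXCLUSION_FLAGS) {
      hit <- if (is.null(visits[[flag]])) rep(FALSE, nrow(visits)) else
        isTRUE_vec(visits[[flag]])
      disposition[paste0("excluded_", flag)] <- sum(hit)
      visits <- visits[!hit, , drop = FALSE]
    }
    no_outcome <- if (is.null(visits$outcome)) rep(TRUE, nrow(visits)) else
      is.na(visits$outcome)
    disposition["excluded_missing_outcome"] <- sum(no_outcome)
    visits <- visits[!no_outcome, , drop = FALSE]
  }
  disposition["included"] <- nrow(visits)
  list(visits = visits, disposition = disposition)
}

merge_records <- function(recs) {
  cols <- unique(unlist(lapply(recs, names)))
  do.call(rbind, lapply(recs, function(r) {
    for (m in setdiff(cols, names(r))) r[[m]] <- NA
    r[cols]
  }))
}

validate_visit_table <- function(visits) {
  missing <- setdiff(c("visit_id", "age_days"), names(visits))
  if (length(missing) > 0L) {
    ped_stop("pedtriage_schema",
             paste0("visit table lacks required column(s): ",
                    paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(visits$visit_id)) {
    ped_stop("pedtriage_schema",
             paste0("duplicate visit_id: ",
                    paste(utils::head(
                      unique(visits$visit_id[duplicated(visits$visit_id)]),
                      5L), collapse = ", ")))
  }
  if (!is.null(visits$sex)) {
    bad <- setdiff(unique(stats::na.omit(visits$sex)), c("male", "female"))
    if (length(bad) > 0L) {
      ped_stop("pedtriage_schema",
               paste0("unknown sex value(s): ", paste(bad, collapse = ", "),
                      "; vocabulary: male, female"))
    }
  }
  if (!is.null(visits$outcome)) {
    bad <- setdiff(unique(stats::na.omit(visits$outcome)), OUTCOME_LEVELS)
    if (length(bad) > 0L) {
      ped_stop("pedtriage_outcome_vocabulary",
               paste0("unknown outcome value(s): ",
                      paste(bad, collapse = ", "), "; vocabulary: ",
                      paste(OUTCOME_LEVELS, collapse = ", ")))
    }
  }
  invisible(visits)
}

#' Write a visit table
#'
#' Inverse of [read_visits()]: CSV with the schema header line, or
#' JSON-lines with a schema header object. Absent values are written as
#' the empty string (CSV) / omitted keys (JSON-lines), never 0.
#'
#' @param visits Visit data frame.
#' @param path Destination.
#' @param dialect `"auto"`, `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path, dialect = c("auto", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
               else "csv"
  }
  validate_visit_table(visits)
  if (dialect == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s v%d", VISIT_SCHEMA, VISIT_SCHEMA_VERSION), con)
    utils::write.csv(visits, con, row.names = FALSE, na = "")
  } else {
    header <- jsonlite::toJSON(list(schema = VISIT_SCHEMA,
                                    version = VISIT_SCHEMA_VERSION,
                                    columns = as.list(names(visits))),
                               auto_unbox = TRUE)
    body <- vapply(seq_len(nrow(visits)), function(i) {
      rec <- as.list(visits[i, , drop = FALSE])
      rec <- rec[!vapply(rec, is.na, logical(1))]
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
    }, character(1))
    writeLines(c(as.character(header), body), path)
  }
  invisible(path)
}

fmt_cell <- function(x, digits = 1) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !is.finite(x)) "NA"
  else sprintf("%.*f", digits, x)
}

fmt_est <- function(est, digits = 1) {
  if (is.null(est)) return("NA")
  if (is.na(est$point) || !is.finite(est$point)) return("NA")
  sprintf("%s (%s-%s)", fmt_cell(est$point, digits),
          fmt_cell(est$lower, digits), fmt_cell(est$upper, digits))
}

#' Render an analysis result as a report table
#'
#' Turns the package's result objects into plain data frames at the
#' reporting precision: percentages and likelihood ratios to one
#' decimal, undefined statistics as the literal `"NA"` (never `0.0`).
#'
#' @param x A `diagnostic_summary`, `triage_crosstab`,
#'   `stratified_validity`, `outcome_summary` or `los_summary`.
#' @param ... Unused.
#' @return A data frame of character/numeric report cells.
#' @export
report_table <- function(x, ...) UseMethod("report_table")

#' @export
report_table.diagnostic_summary <- function(x, digits = 1, ...) {
  stats <- c("sensitivity", "specificity", "ppv", "npv", "lr_pos",
             "lr_neg", "agreement", "over_triage", "under_triage")
  data.frame(statistic = stats,
             point = vapply(stats, function(s) fmt_cell(x[[s]]$point, digits),
                            character(1)),
             lower = vapply(stats, function(s) fmt_cell(x[[s]]$lower, digits),
                            character(1)),
             upper = vapply(stats, function(s) fmt_cell(x[[s]]$upper, digits),
                            character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
report_table.triage_crosstab <- function(x, ...) {
  m <- cbind(unclass(x), Total = rowSums(x))
  m <- rbind(m, Total = colSums(m))
  df <- as.data.frame(m)
  cbind(acuity = rownames(m), df, stringsAsFactors = FALSE,
        row.names = NULL)
}

#' @export
report_table.stratified_validity <- function(x, digits = 1, ...) {
  rows <- lapply(x$reports, function(r) {
    s <- r$summary
    data.frame(stratum = r$stratum, n = r$n,
               test_high = fmt_est(r$prevalence_test_high, digits),
               ref_high = fmt_est(r$prevalence_ref_high, digits),
               sensitivity = fmt_est(if (is.null(s)) NULL else s$sensitivity, digits),
               specificity = fmt_est(if (is.null(s)) NULL else s$specificity, digits),
               ppv = fmt_est(if (is.null(s)) NULL else s$ppv, digits),
               npv = fmt_est(if (is.null(s)) NULL else s$npv, digits),
               lr_pos = fmt_est(if (is.null(s)) NULL else s$lr_pos, digits),
               lr_neg = fmt_est(if (is.null(s)) NULL else s$lr_neg, digits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
report_table.outcome_summary <- function(x, digits = 1, ...) {
  rows <- lapply(names(x$levels), function(l) {
    r <- x$levels[[l]]
    data.frame(level = l, n = r$n,
               icu = fmt_est(r$icu, digits),
               hospitalization = fmt_est(r$hospitalization, digits),
               transfer = fmt_est(r$transfer, digits),
               discharged = fmt_est(r$discharged, digits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
report_table.los_summary <- function(x, digits = 1, ...) {
  data.frame(level = x$groups$level, n = x$groups$n,
             mean = vapply(x$groups$mean, fmt_cell, character(1), digits),
             sd = vapply(x$groups$sd, fmt_cell, character(1), digits),
             stringsAsFactors = FALSE)
}

#' Write a report table to TSV or JSON
#'
#' Deterministic serialization of [report_table()] output: identical
#' input gives byte-identical files, and the TSV and JSON renderings
#' carry numerically identical values (`"NA"` in TSV, `null`-free `"NA"`
#' strings in JSON for undefined statistics).
#'
#' @param x A result object accepted by [report_table()] (or a plain
#'   data frame).
#' @param path Destination file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- if (is.data.frame(x)) x else report_table(x)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "string")
  }
  invisible(path)
}
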