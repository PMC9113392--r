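#' Triage a whole visit table
#'
#' Applies the five-level triage rule to every row of a visit table with
#' vectorized arithmetic (critical shortcut, max-severity item
#' aggregation, risk overrides including the automatic newborn match,
#' vital-sign moderation) and appends `suggested_level`, `final_level`
#' and `fractile_minutes` columns. Semantics are identical to calling
#' [evaluate_triage()] on each row.
#'
#' @param visits Visit data frame with columns `age_days`,
#'   `critical_flag`, `items` (`;`-separated labels), `risk_conditions`
#'   (`;`-separated labels, empty for none) and the vital columns
#'   `glasgow`, `heart_rate`, `resp_rate`, `spo2`, `oxygen_support`.
#' @param config A [triage_config()]; default [default_triage_config()].
#' @return `visits` with the three triage columns appended.
#' @export
triage_cohort <- function(visits, config = default_triage_config()) {
  stopifnot(is.data.frame(visits), inherits(config, "triage_config"))
  n <- nrow(visits)
  critical <- isTRUE_vec(visits$critical_flag)

  # max-severity item aggregation via a label -> level lookup vector
  lv_lookup <- stats::setNames(config$items$items$base_level,
                               config$items$items$label)
  item_lists <- strsplit(ifelse(is.na(visits$items), "", visits$items), ";",
                         fixed = TRUE)
  idx <- rep.int(seq_len(n), lengths(item_lists))
  flat <- unlist(item_lists, use.names = FALSE)
  flat <- trimws(flat)
  keep <- nzchar(flat)
  flat <- flat[keep]; idx <- idx[keep]
  unknown <- flat[!(flat %in% names(lv_lookup))]
  if (length(unknown) > 0L) {
    ped_stop("pedtriage_unknown_item",
             paste0("unknown item label(s): ",
                    paste(unique(unknown), collapse = ", ")))
  }
  suggested <- rep(NA_integer_, n)
  if (length(flat) > 0L) {
    mins <- tapply(lv_lookup[flat], idx, min)
    suggested[as.integer(names(mins))] <- as.integer(mins)
  }
  no_items <- is.na(suggested)
  has_risk <- !is.na(visits$risk_conditions) & nzchar(visits$risk_conditions)
  if (any(no_items & !critical & !has_risk)) {
    ped_stop("pedtriage_no_items",
             paste0("non-critical visits without items or risk conditions ",
                    "at rows: ",
                    paste(utils::head(which(no_items & !critical & !has_risk),
                                      10L), collapse = ", ")))
  }
  suggested[no_items] <- 5L  # risk/critical-only visits start least severe

  # risk overrides: flagged conditions plus automatic age-derived ones
  level <- suggested
  rc <- config$risk_conditions
  risk_lists <- strsplit(ifelse(is.na(visits$risk_conditions), "",
                                visits$risk_conditions), ";", fixed = TRUE)
  for (j in seq_len(nrow(rc))) {
    flagged <- vapply(risk_lists, function(x) rc$label[j] %in% trimws(x),
                      logical(1))
    if (!is.na(rc$age_max_days[j])) {
      flagged <- flagged | visits$age_days < rc$age_max_days[j]
    }
    level[flagged] <- pmin(level[flagged], rc$assigned_level[j])
  }
  risk_fired <- level < suggested

  # vital-sign moderation, joined by age band
  band <- as.character(age_band(visits$age_days))
  rng <- config$vital_ranges
  covered <- band %in% unique(rng$band)
  if (any(!covered)) {
    ped_stop("pedtriage_range_coverage",
             paste0("no vital-sign ranges for the age band of rows: ",
                    paste(utils::head(which(!covered), 10L), collapse = ", ")))
  }
  lvl2 <- level
  for (vital in unique(rng$vital)) {
    v <- rng[rng$vital == vital, ]
    m <- match(band, v$band)
    val <- visits[[vital]]
    if (is.null(val)) next
    out <- !is.na(val) &
      ((!is.na(v$min[m]) & val < v$min[m]) |
         (!is.na(v$max[m]) & val > v$max[m]))
    lvl2[out] <- pmin(lvl2[out], v$escalation_level[m][out])
  }
  final <- ifelse(critical, 1L, lvl2)
  suggested[critical] <- 1L

  visits$suggested_level <- as.integer(suggested)
  visits$final_level <- as.integer(final)
  visits$fractile_minutes <- fractile_target(visits$final_level)
  visits
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Score PEWS for a whole visit table
#'
#' Totals the three PEWS component columns and classifies acuity at the
#' cutoff, appending `pews_total` and `acuity` columns. Missing
#' components are treated as 0 (not assessed = normal).
#'
#' @param visits Visit data frame with `pews_behavior`,
#'   `pews_cardiovascular`, `pews_respiratory` columns.
#' @param cutoff PEWS cutoff, default 4.
#' @return `visits` with `pews_total` and `acuity` appended.
#' @export
pews_cohort <- function(visits, cutoff = 4L) {
  comps <- c("pews_behavior", "pews_cardiovascular", "pews_respiratory")
  stopifnot(all(comps %in% names(visits)))
  vals <- as.matrix(visits[comps])
  vals[is.na(vals)] <- 0
  if (!all(vals %in% 0:3)) {
    ped_stop("pedtriage_component_range",
             "PEWS components must be integers in 0..3 (or NA)")
  }
  visits$pews_total <- as.integer(rowSums(vals))
  visits$acuity <- as.character(classify_acuity(visits$pews_total, cutoff))
  visits
}

#' End-to-end validation of a visit table
#'
#' Runs the full pipeline — triage rule, PEWS scoring, 2x5
#' cross-tabulation, dichotomization, diagnostic summary — on raw
#' visits.
#'
#' @param visits Raw visit data frame (see [triage_cohort()] and
#'   [pews_cohort()] for required columns).
#' @param config A [triage_config()].
#' @param cutoff PEWS cutoff, default 4.
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `validation_result` with `visits` (annotated),
#'   `crosstab`, `confusion` and `summary`.
#' @export
#' @examples
#' v <- generate_cohort(500, seed = 7)
#' validate_cohort(v)$summary
validate_cohort <- function(visits, config = default_triage_config(),
                            cutoff = 4L, conf_level = 0.95) {
  visits <- triage_cohort(visits, config)
  visits <- pews_cohort(visits, cutoff)
  ct <- build_crosstab(visits)
  conf <- dichotomize(ct)
  structure(list(visits = visits, crosstab = ct, confusion = conf,
                 summary = diagnostic_summary(conf, conf_level)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  print(x$crosstab)
  print(x$summary)
  invisible(x)
}
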