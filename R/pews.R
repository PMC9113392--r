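#' Construct PEWS component subscores
#'
#' The Pediatric Early Warning Score rates three components 0--3 each:
#' behavior (alertness and early signs of shock), cardiovascular status
#' (skin tone, capillary refill) and respiratory status (respiratory rate,
#' oxygen dependence).
#'
#' @param behavior,cardiovascular,respiratory Integers in 0..3.
#' @return A named list of class `pews_components`.
#' @export
pews_components <- function(behavior, cardiovascular, respiratory) {
  vals <- c(behavior = behavior, cardiovascular = cardiovascular,
            respiratory = respiratory)
  if (!all(vals %in% 0:3)) {
    ped_stop("pedtriage_component_range",
             "each PEWS component must be an integer in 0..3")
  }
  structure(list(behavior = as.integer(behavior),
                 cardiovascular = as.integer(cardiovascular),
                 respiratory = as.integer(respiratory)),
            class = "pews_components")
}

#' Total a PEWS score from its components
#'
#' @param components A [pews_components()] record.
#' @return An object of class `pews_score` with the three components and
#'   `total` in 0..9.
#' @export
#' @examples
#' total_pews(pews_components(1, 2, 1))$total  # 4
total_pews <- function(components) {
  stopifnot(inherits(components, "pews_components"))
  structure(list(components = components,
                 total = components$behavior + components$cardiovascular +
                   components$respiratory),
            class = "pews_score")
}

#' @export
print.pews_score <- function(x, ...) {
  cat("<pews_score> total ", x$total, "/9 (behavior ",
      x$components$behavior, ", cardiovascular ",
      x$components$cardiovascular, ", respiratory ",
      x$components$respiratory, ")\n", sep = "")
  invisible(x)
}

#' Classify PEWS acuity at a cutoff
#'
#' A total at or above the cutoff (default 4/9) marks a high-level
#' emergency; below it, low-level. Classification depends on the total
#' only, never on how it splits across components.
#'
#' @param score A `pews_score`, or a numeric vector of totals in 0..9.
#' @param cutoff Integer cutoff in 1..9; default 4.
#' @return Factor with levels `c("high", "low")`.
#' @export
#' @examples
#' classify_acuity(total_pews(pews_components(1, 2, 1)))  # high
#' classify_acuity(c(0, 3, 4, 9))
classify_acuity <- function(score, cutoff = 4L) {
  stopifnot(length(cutoff) == 1L, cutoff %in% 1:9)
  total <- if (inherits(score, "pews_score")) score$total else score
  if (!all(total %in% 0:9)) {
    ped_stop("pedtriage_component_range", "PEWS totals must lie in 0..9")
  }
  factor(ifelse(total >= cutoff, "high", "low"), levels = c("high", "low"))
}

#' Default synthetic PEWS rubric
#'
#' Band definitions mapping raw bedside observations to the three 0--3
#' component subscores. Published rubric variants differ between
#' institutions and the variant behind any given validation cohort is
#' rarely printed, so this default is a synthetic stand-in with
#' Monaghan-style bands: it is adequate for exercising the scoring
#' pipeline, not a clinical instrument. Each component lists its bands
#' from least (score 0) to most severe (score 3) with the observation
#' values matching each band.
#'
#' @return A list of class `pews_rubric`: one element per component, each
#'   a list of `list(score =, values =)` bands, plus a `version` string.
#' @export
default_pews_rubric <- function() {
  rub <- list(
    behavior = list(
      list(score = 0L, values = c("playing", "appropriate")),
      list(score = 1L, values = c("sleeping")),
      list(score = 2L, values = c("irritable")),
      list(score = 3L, values = c("lethargic", "confused",
                                  "reduced pain response"))),
    cardiovascular = list(
      list(score = 0L, values = c("pink", "crt 1-2s")),
      list(score = 1L, values = c("pale", "crt 3s")),
      list(score = 2L, values = c("grey", "crt 4s")),
      list(score = 3L, values = c("grey and mottled", "crt 5s+"))),
    respiratory = list(
      list(score = 0L, values = c("normal", "no recession")),
      list(score = 1L, values = c("rr high by 10", "accessory muscles",
                                  "o2 under 4l")),
      list(score = 2L, values = c("rr high by 20", "recession",
                                  "o2 over 4l")),
      list(score = 3L, values = c("rr low below normal", "grunting",
                                  "o2 over 8l"))))
  structure(c(rub, list(version = "synthetic-1.0")), class = "pews_rubric")
}

#' Read a PEWS rubric from YAML or JSON
#'
#' @param path Path to a rubric file with `behavior`, `cardiovascular`
#'   and `respiratory` band lists.
#' @return A `pews_rubric`.
#' @export
read_pews_rubric <- function(path) {
  raw <- read_config_file(path)
  comps <- c("behavior", "cardiovascular", "respiratory")
  if (!all(comps %in% names(raw))) {
    ped_stop("pedtriage_bad_config",
             "rubric must define behavior, cardiovascular and respiratory bands")
  }
  for (comp in comps) {
    raw[[comp]] <- lapply(raw[[comp]], function(b) {
      list(score = as.integer(b$score), values = unlist(b$values))
    })
  }
  structure(raw, class = "pews_rubric")
}

#' Map raw observations to PEWS components through a rubric
#'
#' Each observation string is matched (case-insensitively) against the
#' rubric's bands for its component; the matched band's score is the
#' component subscore. An absent (`NA`) observation scores 0, mirroring
#' the convention that vitals not entered at triage are treated as
#' normal.
#'
#' @param behavior,cardiovascular,respiratory Observation strings, or
#'   `NA` for not assessed.
#' @param rubric A `pews_rubric`; default [default_pews_rubric()].
#' @return A [pews_components()] record.
#' @export
#' @examples
#' components_from_observations("irritable", "pale", NA)  # (2, 1, 0)
components_from_observations <- function(behavior = NA, cardiovascular = NA,
                                         respiratory = NA,
                                         rubric = default_pews_rubric()) {
  stopifnot(inherits(rubric, "pews_rubric"))
  score_one <- function(obs, comp) {
    if (is.na(obs)) return(0L)
    for (band in rubric[[comp]]) {
      if (tolower(obs) %in% tolower(band$values)) return(band$score)
    }
    ped_stop("pedtriage_rubric_coverage",
             sprintf("observation '%s' matches no %s band of the rubric",
                     obs, comp))
  }
  pews_components(score_one(behavior, "behavior"),
                  score_one(cardiovascular, "cardiovascular"),
                  score_one(respiratory, "respiratory"))
}
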