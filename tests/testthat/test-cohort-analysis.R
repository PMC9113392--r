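test_that("stratified confusions pool exactly to the cohort confusion", {
  set.seed(31)
  v <- toy_visits(sample(1:5, 20, replace = TRUE),
                  sample(c(TRUE, FALSE), 20, replace = TRUE))
  v$sex <- sample(c("male", "female"), 20, replace = TRUE)
  v <- pews_cohort(triage_cohort(v))
  sv <- stratified_validity(v, "sex")
  pooled <- dichotomize(build_crosstab(v))
  # brute-force pooling: per-stratum confusions summed cellwise
  sums <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (r in sv$reports) {
    cc <- r$summary$counts
    sums <- sums + c(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn)
  }
  expect_equal(sums, c(tp = pooled$tp, fp = pooled$fp, fn = pooled$fn,
                       tn = pooled$tn))
  expect_equal(sum(vapply(sv$reports, `[[`, numeric(1), "n")) +
                 sv$unclassified, nrow(v))
})

test_that("a single all-cohort stratum reproduces the pooled summary", {
  v <- pews_cohort(triage_cohort(toy_visits(c(1, 2, 3, 4, 5, 2, 3),
                                            c(TRUE, TRUE, FALSE, FALSE,
                                              FALSE, FALSE, TRUE))))
  v$diagnosis <- "all"  # constant stratum covering the whole cohort
  sv <- stratified_validity(v, "diagnosis")
  pooled <- diagnostic_summary(dichotomize(build_crosstab(v)))
  expect_equal(sv$reports[["all"]]$summary$sensitivity$point,
               pooled$sensitivity$point)
  expect_equal(sv$reports[["all"]]$summary$lr_pos$point, pooled$lr_pos$point)
})

test_that("strata with zero denominators report NA, empty strata n = 0", {
  v <- pews_cohort(triage_cohort(toy_visits(c(3, 4, 5), c(FALSE, FALSE,
                                                          FALSE))))
  v$diagnosis <- "flu"
  sv <- stratified_validity(v, "diagnosis", strata = c("flu", "burn"))
  # no reference-high visits: sensitivity undefined
  expect_true(is.na(sv$reports[["flu"]]$summary$sensitivity$point))
  expect_false(is.na(sv$reports[["flu"]]$summary$specificity$point))
  expect_equal(sv$reports[["burn"]]$n, 0L)
  expect_true(is.na(sv$reports[["burn"]]$prevalence_test_high$point))
})

test_that("outcome rates equal a brute-force tally and partition to 100%", {
  v <- toy_visits(rep(c(1, 2), 5), rep(FALSE, 10))
  v$outcome <- c("icu", "hospitalization", "discharged", "discharged",
                 "transfer", "discharged", "hospitalization", "discharged",
                 "discharged", "icu")
  v <- pews_cohort(triage_cohort(v))
  os <- outcome_rates_by_level(v)
  for (l in c(1, 2)) {
    sub <- v[v$final_level == l, ]
    for (o in c("icu", "hospitalization", "transfer", "discharged")) {
      cnt <- 0
      for (i in seq_len(nrow(sub))) if (sub$outcome[i] == o) cnt <- cnt + 1
      expect_equal(os$levels[[paste0("L", l)]][[o]]$point,
                   100 * cnt / nrow(sub))
    }
    pts <- vapply(c("icu", "hospitalization", "transfer", "discharged"),
                  function(o) os$levels[[paste0("L", l)]][[o]]$point,
                  numeric(1))
    expect_equal(sum(pts), 100, tolerance = 1e-12)
  }
  # all-discharged fixture
  v$outcome <- "discharged"
  os <- outcome_rates_by_level(v)
  expect_equal(os$levels$L1$discharged$point, 100)
  expect_equal(os$levels$L1$icu$point, 0)
  v$outcome[1] <- "sent to the moon"
  expect_error(outcome_rates_by_level(v),
               class = "pedtriage_outcome_vocabulary")
})

test_that("synthetic outcome rates track their generating probabilities", {
  params <- default_cohort_params()
  v <- generate_cohort(20000, params, seed = 33)
  v <- pews_cohort(triage_cohort(v))
  os <- outcome_rates_by_level(v)
  # level-2 hospitalization rate within 3 binomial SEs of its parameter
  p <- params$outcome_probs["hospitalization", 2]
  n2 <- os$levels$L2$n
  se <- sqrt(p * (1 - p) / n2)
  expect_lt(abs(os$levels$L2$hospitalization$point / 100 - p), 3 * se)
})

test_that("the ANOVA decomposition matches hand-computed sums of squares", {
  g1 <- c(1, 2, 3); g2 <- c(2, 4, 6); g3 <- c(10, 11, 12)
  v <- data.frame(final_level = rep(1:3, each = 3),
                  los_minutes = c(g1, g2, g3))
  res <- los_anova(v)
  grand <- mean(c(g1, g2, g3))
  ssb <- 3 * ((mean(g1) - grand)^2 + (mean(g2) - grand)^2 +
                (mean(g3) - grand)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$anova$F, f_hand, tolerance = 1e-10)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 6)
  # classical-formula cross-check through stats::oneway.test
  ow <- oneway.test(los_minutes ~ factor(final_level), v, var.equal = TRUE)
  expect_equal(res$anova$F, unname(ow$statistic), tolerance = 1e-10)
  expect_equal(res$anova$p_value, unname(ow$p.value), tolerance = 1e-10)
})

test_that("ANOVA edge cases: equal groups give F = 0, null gives large p", {
  v <- data.frame(final_level = rep(1:3, each = 4),
                  los_minutes = rep(c(5, 6, 7, 8), times = 3))
  expect_equal(los_anova(v)$anova$F, 0, tolerance = 1e-12)
  # all groups from one distribution: p well above the 0.001 level
  set.seed(35)
  ps <- replicate(10, {
    v <- data.frame(final_level = rep(1:4, each = 25),
                    los_minutes = rnorm(100, 120, 40))
    los_anova(v)$anova$p_value
  })
  expect_gt(median(ps), 0.05)
  expect_true(all(ps > 0.001 / 2))
})

test_that("ANOVA drops tiny groups with a warning and needs two groups", {
  v <- data.frame(final_level = c(1, 1, 1, 2, 3, 3, 3),
                  los_minutes = c(10, 12, 14, 99, 20, 22, 24))
  expect_warning(res <- los_anova(v), class = "pedtriage_small_group")
  expect_equal(res$groups$level, c("1", "3"))
  expect_error(suppressWarnings(
    los_anova(data.frame(final_level = c(1, 1, 2),
                         los_minutes = c(1, 2, 3)))),
    class = "pedtriage_insufficient_groups")
})

test_that("Scheffe contrasts are symmetric and detect separated groups", {
  set.seed(36)
  v <- data.frame(final_level = rep(1:3, each = 30),
                  los_minutes = c(rnorm(30, 200, 10), rnorm(30, 120, 10),
                                  rnorm(30, 60, 10)))
  res <- los_anova(v)
  sc <- res$scheffe
  expect_equal(sc$upper - sc$diff, sc$diff - sc$lower, tolerance = 1e-10)
  expect_true(all(sc$significant))
  # contrast interval excludes zero iff flagged significant
  expect_equal(sc$significant, sc$lower > 0 | sc$upper < 0)
})
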