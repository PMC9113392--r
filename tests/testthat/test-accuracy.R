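test_that("crosstabs count visits cell by cell", {
  # empty and single-visit cases
  empty <- data.frame(final_level = integer(), acuity = character())
  expect_equal(attr(build_crosstab(empty), "n"), 0)
  one <- data.frame(final_level = 2L, acuity = "high")
  ct1 <- build_crosstab(one)
  expect_equal(unname(ct1["high", 2]), 1)
  expect_equal(sum(ct1), 1)
  # 10-visit fixture vs brute-force tally
  set.seed(21)
  v <- data.frame(final_level = sample(1:5, 10, replace = TRUE),
                  acuity = sample(c("high", "low"), 10, replace = TRUE))
  ct <- build_crosstab(v)
  for (a in c("high", "low")) {
    for (l in 1:5) {
      cnt <- 0
      for (i in 1:10) {
        if (v$acuity[i] == a && v$final_level[i] == l) cnt <- cnt + 1
      }
      expect_equal(unname(ct[a, l]), cnt)
    }
  }
  expect_error(build_crosstab(data.frame(final_level = c(1, NA),
                                         acuity = c("high", "low"))),
               class = "pedtriage_incomplete_visit")
})

test_that("dichotomization pools levels 1-2 vs 3-5 and conserves n", {
  conf <- dichotomize(refcohort_crosstab())
  expect_equal(conf$tp, 1710)
  expect_equal(conf$fn, 528)
  expect_equal(conf$fp, 15082)
  expect_equal(conf$tn, 83186)
  expect_equal(conf$tp + conf$fp + conf$fn + conf$tn, 100506)
  # all-zero and single-cell partition properties
  z <- dichotomize(crosstab(matrix(0, 2, 5)))
  expect_equal(unlist(z[c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 0, tn = 0))
  single <- matrix(0, 2, 5); single[2, 4] <- 7
  s <- dichotomize(crosstab(single))
  expect_equal(sort(unlist(s[c("tp", "fp", "fn", "tn")])),
               c(tp = 0, fp = 0, fn = 0, tn = 7), ignore_attr = TRUE)
  expect_equal(sum(unlist(s[c("tp", "fp", "fn", "tn")]) == 7), 1)
})

test_that("diagnostic summaries match brute-force formulas on random tables", {
  set.seed(22)
  for (i in 1:25) {
    tp <- sample(1:50, 1); fp <- sample(1:50, 1)
    fn <- sample(1:50, 1); tn <- sample(1:50, 1)
    s <- diagnostic_summary(confusion_2x2(tp, fp, fn, tn))
    b <- brute_summary(tp, fp, fn, tn)
    expect_equal(s$sensitivity$point, b$sens, tolerance = 1e-12)
    expect_equal(s$specificity$point, b$spec, tolerance = 1e-12)
    expect_equal(s$ppv$point, b$ppv, tolerance = 1e-12)
    expect_equal(s$npv$point, b$npv, tolerance = 1e-12)
    expect_equal(s$lr_pos$point, b$lr_pos, tolerance = 1e-12)
    expect_equal(s$lr_neg$point, b$lr_neg, tolerance = 1e-12)
    expect_equal(s$agreement$point, b$agreement, tolerance = 1e-12)
    expect_equal(s$over_triage$point, b$over, tolerance = 1e-12)
    expect_equal(s$under_triage$point, b$under, tolerance = 1e-12)
    # LR identity on points, to machine precision
    expect_equal(s$lr_pos$point,
                 s$sensitivity$point / (100 - s$specificity$point),
                 tolerance = 1e-12)
    # agreement + over + under = 100
    expect_equal(s$agreement$point + s$over_triage$point +
                   s$under_triage$point, 100, tolerance = 1e-12)
  }
})

test_that("degenerate confusion tables give NA statistics, never zero", {
  perfect <- diagnostic_summary(confusion_2x2(5, 0, 0, 7))
  expect_equal(perfect$sensitivity$point, 100)
  expect_equal(perfect$specificity$point, 100)
  expect_equal(perfect$agreement$point, 100)
  expect_equal(perfect$over_triage$point, 0)
  s <- diagnostic_summary(confusion_2x2(0, 0, 5, 5))
  expect_true(is.na(s$ppv$point))
  expect_equal(s$sensitivity$point, 0)
  expect_error(diagnostic_summary(confusion_2x2(0, 0, 0, 0)),
               class = "pedtriage_empty_table")
})

test_that("exact intervals match the binom.test oracle", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:400, 1)
    x <- sample(0:n, 1)
    est <- proportion_ci(x, n)
    oracle <- stats::binom.test(x, n)$conf.int
    expect_equal(est$lower, oracle[1], tolerance = 1e-10)
    expect_equal(est$upper, oracle[2], tolerance = 1e-10)
  }
})

test_that("Wilson intervals match prop.test and a root-finding oracle", {
  # prop.test with correct = FALSE computes the Wilson score interval
  set.seed(24)
  for (i in 1:20) {
    n <- sample(5:500, 1)
    x <- sample(1:(n - 1), 1)
    est <- proportion_ci(x, n, method = "wilson")
    oracle <- suppressWarnings(stats::prop.test(x, n, correct = FALSE))$conf.int
    expect_equal(est$lower, oracle[1], tolerance = 1e-9)
    expect_equal(est$upper, oracle[2], tolerance = 1e-9)
  }
  # independent root-finder: solve (phat - p) / sqrt(p(1-p)/n) = +/- z
  x <- 7; n <- 19; phat <- x / n; z <- qnorm(0.975)
  f <- function(p, sign) (phat - p) / sqrt(p * (1 - p) / n) - sign * z
  lower <- uniroot(f, c(1e-9, phat), sign = 1, tol = 1e-12)$root
  upper <- uniroot(f, c(phat, 1 - 1e-9), sign = -1, tol = 1e-12)$root
  est <- proportion_ci(x, n, method = "wilson")
  expect_equal(est$lower, lower, tolerance = 1e-8)
  expect_equal(est$upper, upper, tolerance = 1e-8)
  # structural properties: contains the point, shrinks with n at fixed x/n
  w1 <- proportion_ci(10, 40, method = "wilson")
  w2 <- proportion_ci(100, 400, method = "wilson")
  expect_true(w1$lower <= w1$point && w1$point <= w1$upper)
  expect_lt(w2$upper - w2$lower, w1$upper - w1$lower)
  expect_equal(proportion_ci(15, 15)$upper, 1)
  expect_error(proportion_ci(1, 0), class = "pedtriage_empty")
})

test_that("likelihood-ratio intervals use the log method and flag zeros", {
  conf <- dichotomize(refcohort_crosstab())
  lrp <- likelihood_ratio_ci(conf, "positive")
  # independent recomputation of the log-method formula
  sens <- 1710 / 2238; spec <- 83186 / 98268
  se <- sqrt(1 / 1710 - 1 / 2238 + 1 / 15082 - 1 / 98268)
  z <- qnorm(0.975)
  expect_equal(lrp$point, sens / (1 - spec), tolerance = 1e-12)
  expect_equal(lrp$lower, exp(log(sens / (1 - spec)) - z * se),
               tolerance = 1e-12)
  expect_equal(lrp$upper, exp(log(sens / (1 - spec)) + z * se),
               tolerance = 1e-12)
  # symmetric toy table: LR+ = 1 and the interval contains 1
  toy <- confusion_2x2(10, 10, 20, 20)
  lr1 <- likelihood_ratio_ci(toy, "positive")
  expect_equal(lr1$point, 1, tolerance = 1e-12)
  expect_true(lr1$lower <= 1 && 1 <= lr1$upper)
  # zero cell -> NA with a reason
  z0 <- likelihood_ratio_ci(confusion_2x2(0, 5, 5, 5), "positive")
  expect_true(is.na(z0$point))
  expect_match(attr(z0, "reason"), "zero cell")
})

test_that("chi-squared equals the O/E enumeration and handles edge cases", {
  # proportional rows: independence, statistic 0
  prop_tab <- rbind(c(10, 20, 30), c(20, 40, 60))
  res <- chi_squared_test(prop_tab)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  # direct O/E enumeration oracle on a 2x2 table
  tab <- rbind(c(10, 20), c(20, 10))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- rs[i] * cs[j] / n
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  res <- chi_squared_test(tab)
  expect_equal(res$statistic, unname(stat), tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_error(chi_squared_test(rbind(c(0, 0), c(1, 2))),
               class = "pedtriage_degenerate_margin")
  expect_error(chi_squared_test(matrix(1:3, 1)),
               class = "pedtriage_degenerate_margin")
})

test_that("Bonferroni divides the 0.001 family-wise level", {
  expect_equal(bonferroni_threshold(5), 0.0002)
  expect_equal(bonferroni_threshold(1), 0.001)
  expect_equal(bonferroni_threshold(4, alpha = 0.05), 0.0125)
})

test_that("ordinal over/under-triage reading differs only as documented", {
  ct <- refcohort_crosstab()
  dich <- over_under_counts(ct)
  expect_equal(unname(dich["over"]), 15082)
  expect_equal(unname(dich["under"]), 528)
  expect_equal(sum(dich), attr(ct, "n"))
  ord <- over_under_counts(ct, scale = "ordinal")
  expect_equal(sum(ord), attr(ct, "n"))
  # ordinal counts a high-acuity level-1 assignment as over-triage too
  expect_equal(unname(ord["over"]), 82 + 15082)
})
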