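test_that("Pearson chi-square matches the closed-form oracle and known tables", {
  expect_equal(round(pearsonChiSquare(matrix(c(28, 3, 62, 32), 2))$p.value, 4),
               0.0088)
  flat <- pearsonChiSquare(matrix(c(10, 20, 10, 20), 2))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 1)
  set.seed(13)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 30) + 5, 2)
    res <- suppressWarnings(pearsonChiSquare(tab))
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    expect_equal(unname(res$statistic), stat, tolerance = 1e-12)
    expect_equal(res$p.value, pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    # invariance to transposition and row/column permutation
    expect_equal(suppressWarnings(pearsonChiSquare(t(tab)))$p.value,
                 res$p.value)
    expect_equal(suppressWarnings(pearsonChiSquare(tab[2:1, 2:1]))$p.value,
                 res$p.value)
  }
  expect_error(pearsonChiSquare(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_warning(pearsonChiSquare(matrix(c(2, 3, 50, 50), 2)), "below 5")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  fisherOracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    x <- 0:min(m, k)
    d <- dhyper(x, m, n, k)
    sum(d[d <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  }
  tab <- matrix(c(1, 9, 9, 1), 2)
  expect_equal(fisherExact(tab)$p.value, fisherOracle(tab), tolerance = 1e-10)
  set.seed(17)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisherExact(tab)$p.value, fisherOracle(tab),
                 tolerance = 1e-8)
  }
  expect_equal(fisherExact(matrix(5, 2, 2))$p.value, 1)
  expect_error(fisherExact(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(fisherExact(matrix(1, 3, 3)), "2 x 2")
})

test_that("the product-limit estimator behaves at the edges and matches survfit", {
  censOnly <- kmEstimate(1:10, rep(0, 10))
  expect_equal(kmSurvival(censOnly, c(0, 5, 100)), c(1, 1, 1))
  one <- kmEstimate(c(2, 5, 7, 9), c(1, 0, 0, 0))
  expect_equal(kmSurvival(one, 2), 0.75)
  expect_equal(kmSurvival(one, 1.9), 1)
  expect_error(kmEstimate(c(-1, 2), c(1, 0)), "negative")
  set.seed(19)
  times <- round(rexp(50, 0.05), 1)
  events <- rbinom(50, 1, 0.6)
  mine <- kmEstimate(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  oracle <- summary(fit, times = mine$time)
  expect_equal(mine$survival, oracle$surv, tolerance = 1e-10)
  expect_equal(mine$nRisk, oracle$n.risk, tolerance = 1e-10)
  # merged identical groups have the same curve as each group
  both <- kmEstimate(c(times, times), c(events, events))
  expect_equal(both$survival, mine$survival, tolerance = 1e-12)
})

test_that("the log-rank test matches survdiff and is symmetric", {
  t1 <- c(6, 13, 21, 30, 31, 37, 38, 47, 49, 50)
  e1 <- c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0)
  t2 <- c(10, 20, 25, 28, 40, 45, 50, 60, 70, 80)
  e2 <- c(1, 1, 0, 1, 1, 0, 1, 0, 0, 0)
  same <- logrankTest(t1, e1, t1, e1)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(logrankTest(1:3, c(0, 0, 0), 4:6, c(0, 0, 0)), "no events")
  mine <- logrankTest(t1, e1, t2, e2)
  sd <- survival::survdiff(
    survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, each = 10))
  expect_equal(unname(mine$statistic), sd$chisq, tolerance = 1e-8)
  expect_equal(mine$p.value, pchisq(sd$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  set.seed(23)
  for (i in 1:10) {
    ta <- rexp(30, 0.04); ea <- rbinom(30, 1, 0.7)
    tb <- rexp(25, 0.08); eb <- rbinom(25, 1, 0.7)
    if (sum(ea) + sum(eb) == 0) next
    mine <- logrankTest(ta, ea, tb, eb)
    sd <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(30, 25)))
    expect_equal(unname(mine$statistic), sd$chisq, tolerance = 1e-8)
  }
})

test_that("the ROC threshold maximizes Youden's J like exhaustive search", {
  expect_equal(rocBestThreshold(c(-3, -2, 2, 3), c(TRUE, TRUE, FALSE, FALSE),
                                positiveIsLow = TRUE), 0)
  expect_error(rocBestThreshold(1:4, rep(TRUE, 4)), "both label classes")
  expect_error(rocBestThreshold(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE)),
               "identical")
  jOf <- function(cut, scores, labels, low) {
    pred <- if (low) scores < cut else scores > cut
    sum(pred & labels) / sum(labels) + sum(!pred & !labels) / sum(!labels) - 1
  }
  set.seed(29)
  for (i in 1:20) {
    scores <- round(rnorm(10), 2)
    labels <- scores + rnorm(10, sd = 0.5) < 0
    if (length(unique(labels)) < 2 || length(unique(scores)) < 2) next
    low <- i %% 2 == 0
    thr <- rocBestThreshold(scores, labels, positiveIsLow = low)
    u <- sort(unique(scores))
    cuts <- (u[-1] + u[-length(u)]) / 2
    bestJ <- max(vapply(cuts, jOf, 0, scores = scores, labels = labels,
                        low = low))
    expect_equal(jOf(thr, scores, labels, low), bestJ, tolerance = 1e-12)
  }
})

test_that("the association scan reproduces table-style pairwise tests", {
  gen <- generateCohort(generatorConfig(n = 120, seed = 4))
  f <- callFeatures(gen$cohort)
  scan <- suppressWarnings(associationScan(gen$cohort, f))
  expect_true(all(c("feature", "covariate", "p_value") %in% colnames(scan)))
  expect_true(all(scan$p_value >= 0 & scan$p_value <= 1))
  tables <- attr(scan, "tables")
  # each reported p recomputes from its own stored table
  for (key in sample(names(tables), 5)) {
    res <- suppressWarnings(pearsonChiSquare(tables[[key]]))
    expect_equal(scan$p_value[paste(scan$feature, scan$covariate,
                                    sep = "|") == key], res$p.value)
  }
  # subclass (2x4-style) scan works through the same interface
  f$subclass <- subclassify(f)$subclass
  scan4 <- suppressWarnings(associationScan(gen$cohort, f,
                                            featureCols = "subclass"))
  expect_true(all(scan4$df %in% c(1, 2, 3)))
})
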