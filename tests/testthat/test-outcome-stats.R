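test_that("ROC handles separation, ties and permutations by contract", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  perm <- c(3, 1, 4, 2)
  expect_equal(rocAuc(c(0.8, 0.3, 0.5, 0.1)[perm], c(1, 1, 0, 0)[perm])$auc,
               0.75)
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney statistic", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(10:40, 1)
      y <- c(rep(1, 5), rbinom(n - 5, 1, 0.4))
      s <- round(rnorm(n), 1)          # rounding forces ties
    })
    if (length(unique(y)) < 2) next
    auc <- rocAuc(s, y)$auc
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("ROC cutoff maximizes Youden's J", {
  s <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  y <- c(1, 1, 0, 1, 0, 0)
  roc <- rocAuc(s, y)
  js <- vapply(unique(s), function(cut) {
    cm <- confusionMetrics(s > cut, y)
    cm$sensitivity + cm$specificity - 1
  }, 0)
  expect_equal(roc$youden, max(js))
})

test_that("confusion metrics reproduce the printed study percentages", {
  pred <- rep(c(TRUE, FALSE, TRUE, FALSE), c(18, 4, 4, 38))
  truth <- rep(c(TRUE, TRUE, FALSE, FALSE), c(18, 4, 4, 38))
  cm <- confusionMetrics(pred, truth)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(18, 4, 4, 38))
  expect_equal(round(100 * cm$sensitivity, 1), 81.8)
  expect_equal(round(100 * cm$specificity, 1), 90.5)
  expect_equal(round(100 * cm$fpr, 1), 9.5)
  expect_equal(round(100 * cm$fnr, 1), 18.2)
  all_right <- confusionMetrics(truth, truth)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  none <- confusionMetrics(rep(FALSE, length(truth)), truth)
  expect_equal(none$tp, 0)
  expect_equal(none$sensitivity, 0)
  expect_error(confusionMetrics(c(TRUE, FALSE), TRUE), "length")
})

test_that("Wilcoxon rank-sum matches exact enumeration and symmetry", {
  r <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(r$p.value, 1 / 3, tolerance = 1e-12)   # 2 of C(4,2) orders
  expect_equal(r$statistic, 0)
  same <- wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)                   # nm/2
  expect_gt(same$p.value, 0.9)
  far <- wilcoxonRankSum(1:4, 101:104)
  expect_equal(far$p.value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
})

test_that("Kaplan-Meier steps follow the product-limit closed form", {
  km <- kmLogrank(time = c(1, 2, 3, 4, 5, 6, 7, 8),
                  event = rep(1, 8),
                  group = rep(c("a", "b"), each = 4))
  a <- km$curves[km$curves$group == "a", ]
  expect_equal(a$surv, c(0.75, 0.5, 0.25, 0))
  # identical groups: chi-square 0, p = 1
  km0 <- kmLogrank(time = rep(c(2, 4, 6), 2), event = rep(1, 6),
                   group = rep(c("x", "y"), each = 3))
  expect_lt(km0$chisq, 1e-10)
  expect_equal(km0$p.value, 1, tolerance = 1e-6)
  # censored-only group stays flat at 1
  kmc <- kmLogrank(time = c(1, 2, 3, 1, 2, 3),
                   event = c(0, 0, 0, 1, 1, 1),
                   group = rep(c("c", "d"), each = 3))
  expect_true(all(kmc$curves$surv[kmc$curves$group == "c"] == 1))
  expect_error(kmLogrank(1:3, c(1, 1, 1), factor(rep("a", 3),
                                                 levels = c("a", "b"))),
               "group")
})

test_that("KM without censoring equals the empirical survival function", {
  withr::with_seed(31L, {
    t1 <- rexp(40); t2 <- rexp(40, 1.5)
  })
  km <- kmLogrank(c(t1, t2), rep(1, 80), rep(c("g1", "g2"), each = 40))
  c1 <- km$curves[km$curves$group == "g1", ]
  emp <- vapply(c1$time, function(u) mean(t1 > u), 0)
  expect_equal(c1$surv, emp, tolerance = 1e-12)
})

test_that("log-rank keeps nominal type-I error on permuted null data", {
  withr::with_seed(77L, {
    time <- rexp(60)
    event <- rbinom(60, 1, 0.8)
    p <- vapply(1:1000, function(i) {
      g <- sample(rep(0:1, each = 30))
      kmLogrank(time, event, g)$p.value
    }, 0)
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("Cox HR matches a brute-force partial-likelihood maximizer", {
  withr::with_seed(5L, {
    x <- rbinom(10, 1, 0.5)
    time <- rexp(10, exp(0.8 * x))
  })
  d <- data.frame(df_months = time, recurrence_event = 1, x = x)
  fit <- coxPH(d, "x")
  bruteBeta <- stats::optimize(function(b)
    -coxPartialLogLik(b, time, x), c(-5, 5))$minimum
  expect_equal(log(fit$hr), bruteBeta, tolerance = 1e-4)
  expect_true(fit$ciLow <= fit$hr && fit$hr <= fit$ciHigh)
})

test_that("Cox point estimate is replication-invariant with a tighter CI", {
  withr::with_seed(6L, {
    x <- rbinom(40, 1, 0.5)
    time <- rexp(40, exp(0.7 * x))
  })
  d <- data.frame(df_months = time, recurrence_event = 1, x = x)
  one <- coxPH(d, "x")
  two <- coxPH(rbind(d, d), "x")
  # duplication introduces ties, so Efron handling perturbs the
  # maximizer slightly; the point estimate must stay close and the CI
  # must tighten
  expect_equal(two$hr, one$hr, tolerance = 0.05)
  expect_lt(two$ciHigh - two$ciLow, one$ciHigh - one$ciLow)
})

test_that("Cox rejects zero-variance covariates and flags separation", {
  d <- data.frame(df_months = rexp(10), recurrence_event = 1,
                  x = rep(1, 10))
  expect_error(coxPH(d, "x"), "zero-variance")
  expect_error(coxPH(data.frame(df_months = 1:3,
                                recurrence_event = c(1, 0, 0),
                                x = c(1, 0, 1)), "x"), "2 events")
})

test_that("Cox confidence intervals cover a known hazard ratio", {
  hits <- vapply(1:200, function(seed) {
    withr::with_seed(1000L + seed, {
      x <- rep(0:1, each = 100)
      time <- rexp(200, exp(log(3) * x))
    })
    d <- data.frame(df_months = time, recurrence_event = 1, x = x)
    fit <- coxPH(d, "x")
    fit$ciLow <= 3 && 3 <= fit$ciHigh
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("multivariate Cox returns one row per term jointly fitted", {
  co <- generateCohort(cohortSimParams(seed = 14L))
  rec <- cohortRecords(co)
  fit <- coxPH(rec, c("meld", "vascular_invasion", "tumor_size_cm"),
               mode = "multivariate")
  expect_equal(nrow(fit), 3)
  expect_true(all(fit$model == "multivariate"))
  expect_true(all(fit$hr > 0, na.rm = TRUE))
})

test_that("Pearson correlation matches direct formula evaluation", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 5, 5, 9)
  r <- pearsonCorr(x, y)
  expect_equal(r$r, sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_equal(pearsonCorr(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorr(x, -x)$r, -1)
  expect_error(pearsonCorr(x, rep(2, 5)), "zero-variance")
})

test_that("stratum summaries report counts and one-decimal percentages", {
  d <- data.frame(
    g = rep(c("high", "low"), c(22, 42)),
    death = c(rep(1, 16), rep(0, 6), rep(1, 9), rep(0, 33)))
  s <- stratumSummary(d, "g", "death")
  expect_equal(s$patients, c(22, 42))
  expect_equal(s$events, c(16, 9))
  expect_equal(s$percent, c(72.7, 21.4))
  # empty stratum reported with 0 and omitted percent
  d$g <- factor(d$g, levels = c("high", "low", "none"))
  s2 <- stratumSummary(d, "g", "death")
  expect_equal(s2$patients[3], 0)
  expect_true(is.na(s2$percent[3]))
  expect_equal(stratumSummary(data.frame(g = "a", death = 0),
                              "g", "death")$percent, 0)
})
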