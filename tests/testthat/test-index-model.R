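test_that("min-max normalization follows the formula with its conventions", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  p <- fitNormalization(x)
  xn <- applyNormalization(x, p)
  expect_equal(unname(xn[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(xn[, "b"]), c(0, 0, 0))     # constant maps to 0
  # clipping of unseen values
  new <- applyNormalization(cbind(a = c(8, 1), b = c(9, 9)), p)
  expect_equal(unname(new[, "a"]), c(1, 0))
  expect_error(applyNormalization(
    data.frame(a = "x", b = 1), p), "non-numeric")
})

test_that("forward selection finds a single dominant feature first", {
  x <- toyTable(64, 176, seed = 1L)
  y <- 2 * x[, 42]
  sel <- sequentialForwardSelection(x, y, kMax = 1)
  expect_identical(sel, colnames(x)[42])
})

test_that("forward selection with k = 2 matches the exhaustive pair oracle", {
  for (seed in 1:5) {
    x <- toyTable(40, 10, seed = seed)
    y <- x[, 2] + x[, 7]   # noiseless two-feature signal
    sel <- sequentialForwardSelection(x, y, kMax = 2)
    # oracle: best pair by exhaustive search
    pairs <- utils::combn(10, 2)
    rss <- apply(pairs, 2, function(ij)
      rssOf(x[, ij, drop = FALSE], y))
    best <- sort(pairs[, which.min(rss)])
    expect_setequal(sel, colnames(x)[best])
  }
})

test_that("forward selection respects kMax, pools and tie-break order", {
  x <- toyTable(30, 8, seed = 3L)
  y <- rnorm(30)
  expect_length(sequentialForwardSelection(x, y, kMax = 0), 0)
  sel <- sequentialForwardSelection(x, y, kMax = 3,
                                    pool = colnames(x)[c(5, 2, 8)])
  expect_true(all(sel %in% colnames(x)[c(5, 2, 8)]))
  # duplicated column: exact RSS tie broken by pool order, copy skipped
  x2 <- cbind(x, dup = x[, 1])
  y2 <- 3 * x2[, 1]
  expect_warning(sel2 <- sequentialForwardSelection(x2, y2, kMax = 2),
                 "collinear")
  expect_equal(sel2[1], colnames(x)[1])
})

test_that("OLS index fit matches the normal-equations oracle", {
  for (seed in 1:5) {
    x <- toyTable(20, 3, seed = 10L + seed)
    y <- withr::with_seed(99L + seed, rnorm(20))
    m <- fitLinearIndex(x, y)
    X1 <- cbind(1, x)
    beta <- solve(t(X1) %*% X1, t(X1) %*% y)
    expect_equal(intercept(m), beta[1], tolerance = 1e-8)
    expect_equal(unname(coef(m)[-1]), unname(beta[-1, 1]),
                 tolerance = 1e-8)
  }
  # noiseless interpolation is exact
  x <- cbind(x1 = seq(0, 1, length.out = 12), x2 = runif(12))
  m <- fitLinearIndex(x, 0.5 + 0.2 * x[, 1])
  expect_equal(intercept(m), 0.5, tolerance = 1e-12)
  expect_equal(unname(coef(m)["x1"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(coef(m)["x2"]), 0, tolerance = 1e-12)
  # all-zero response
  m0 <- fitLinearIndex(x, rep(0, 12))
  expect_true(all(abs(coef(m0)) < 1e-12))
  # singular design is an error naming the offender
  xs <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fitLinearIndex(xs, rnorm(10)), "singular.*b")
})

test_that("LOOCV fits n fold models and honours the leave-one-out closed form", {
  n <- 24L
  x <- cbind(const = rep(1, n))
  y <- withr::with_seed(4L, rnorm(n))
  pred <- loocvPredict(x, y, kMax = 1)
  expect_equal(attr(pred, "nFolds"), n)
  loo <- vapply(seq_len(n), function(i) mean(y[-i]), 0)
  expect_equal(as.numeric(pred), loo, tolerance = 1e-10)
})

test_that("LOOCV predictions are invariant to row order", {
  co <- generateCohort(cohortSimParams(n = 24L, prevalenceEarly = 0.375,
                                       seed = 6L))
  x <- cohortFeatures(co)
  y <- cohortRecords(co)$early_recurrence
  p1 <- loocvPredict(x, y, kMax = 4)
  perm <- withr::with_seed(8L, sample(nrow(x)))
  p2 <- loocvPredict(x[perm, ], y[perm], kMax = 4)
  expect_equal(as.numeric(p2), as.numeric(p1)[perm], tolerance = 1e-10)
  expect_error(loocvPredict(x[1:2, ], y[1:2]), "at least 3")
})

test_that("nested LOOCV re-selects per fold and stays sane", {
  co <- generateCohort(cohortSimParams(n = 20L, prevalenceEarly = 0.35,
                                       seed = 9L))
  x <- cohortFeatures(co)[, 1:30]
  y <- cohortRecords(co)$early_recurrence
  pred <- loocvPredict(x, y, kMax = 2, mode = "nested")
  expect_equal(attr(pred, "nFolds"), 20L)
  expect_length(attr(pred, "selected"), 20L)
  expect_true(all(is.finite(pred)))
})

test_that("the shipped published model reproduces its printed arithmetic", {
  m <- publishedCombinedModel()
  expect_length(indexFeatures(m), 18)
  expect_equal(sum(grepl("/", indexFeatures(m))), 9)
  expect_equal(intercept(m), 3.838)
  zero <- stats::setNames(rep(0, 18), indexFeatures(m))
  one <- stats::setNames(rep(1, 18), indexFeatures(m))
  expect_equal(scoreIndex(zero, m), 3.838)
  expect_equal(scoreIndex(one, m), -3.237, tolerance = 1e-12)
  expect_equal(riskCutoff(m), 0.501)
})

test_that("risk classification is strict at the published cutoff", {
  expect_identical(as.character(classifyRisk(c(0.564, 0.121, 0.501, 0.502))),
                   c("high", "low", "low", "high"))
})

test_that("scoring rejects vectors missing model features", {
  m <- publishedCombinedModel()
  v <- stats::setNames(rep(0, 17), indexFeatures(m)[-1])
  expect_error(scoreIndex(v, m), indexFeatures(m)[1], fixed = TRUE)
})

test_that("models round-trip through JSON", {
  co <- generateCohort(cohortSimParams(n = 30L, prevalenceEarly = 0.3,
                                       seed = 12L))
  m <- suppressWarnings(
    trainIndexModel(cohortFeatures(co),
                    cohortRecords(co)$early_recurrence, kMax = 4))
  path <- file.path(withr::local_tempdir(), "model.json")
  writeIndexModel(m, path)
  r <- readIndexModel(path)
  expect_identical(indexFeatures(r), indexFeatures(m))
  expect_equal(coef(r), coef(m))
  expect_equal(riskCutoff(r), riskCutoff(m))
  v <- cohortFeatures(co)[3, ]
  expect_equal(scoreIndex(v, r), scoreIndex(v, m))
})

test_that("selection recovers a planted noiseless linear signal", {
  # quasi-independent candidates: greedy selection provably recovers the
  # planted subset and OLS converges to the planted coefficients
  x <- toyTable(64, 20, seed = 20L)
  beta <- c(F004 = 0.8, F011 = -0.6, F017 = 0.5)
  y <- drop(x[, names(beta)] %*% beta)
  sel <- sequentialForwardSelection(x, y, kMax = 3)
  expect_setequal(sel, names(beta))
  m <- fitLinearIndex(x[, sel], y)
  expect_equal(coef(m)[names(beta)], beta, tolerance = 1e-10)
  expect_equal(unname(intercept(m)), 0, tolerance = 1e-10)
  # in the cohort table (correlated features) the greedy fit must still
  # explain the noiseless latent index essentially exactly
  p <- cohortSimParams(noiseSd = 0, seed = 20L)
  co <- generateCohort(p)
  xn <- applyNormalization(cohortFeatures(co),
                           fitNormalization(cohortFeatures(co)))
  latent <- S4Vectors::metadata(co)$latentIndex
  sel2 <- suppressWarnings(
    sequentialForwardSelection(xn, latent, kMax = 8))
  res <- stats::residuals(stats::lm(latent ~ xn[, sel2]))
  expect_gt(1 - sum(res^2) / sum((latent - mean(latent))^2), 0.99)
})
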