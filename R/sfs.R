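# Sequential forward selection under a residual sum-of-squares criterion,
# ordinary least-squares index fitting, and leave-one-out cross-validation.

# OLS with intercept; rank-deficient designs get NA coefficients zeroed
.olsFit <- function(X, y) {
  X1 <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(X1, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(intercept = beta[1], coefficients = beta[-1],
       rss = sum(fit$residuals^2), rank = fit$rank, p = ncol(X1))
}

#' Sequential forward selection by residual sum of squares
#'
#' Greedy forward search: starting from the empty set, at each step add
#' the candidate feature whose inclusion in the intercepted linear model
#' of `y` minimizes the residual sum of squares, until `kMax` features are
#' selected. Ties are broken in favour of the candidate earliest in pool
#' (taxonomy) order; a candidate whose addition makes the design singular
#' is skipped with a warning.
#'
#' @param x numeric matrix/data.frame, samples in rows, candidate features
#'   in columns (typically min-max normalized; no missing values).
#' @param y numeric response (the 0/1 early-recurrence label).
#' @param kMax number of features to select; must be < `nrow(x)`.
#' @param pool optional character vector restricting (and ordering) the
#'   candidate features; defaults to all columns of `x` in column order.
#' @return character vector of selected feature names, in selection order.
#' @export
sequentialForwardSelection <- function(x, y, kMax, pool = NULL) {
  x <- .asFeatureMatrix(x)
  stopifnot(length(y) == nrow(x), !anyNA(y))
  kMax <- as.integer(kMax)
  if (kMax >= nrow(x))
    stop("kMax must be smaller than the number of samples")
  if (is.null(pool)) pool <- colnames(x)
  missing <- setdiff(pool, colnames(x))
  if (length(missing))
    stop("pool features absent from table: ",
         paste(missing, collapse = ", "))
  selected <- character(0)
  remaining <- pool
  while (length(selected) < kMax && length(remaining) > 0) {
    best <- NULL; bestRss <- Inf
    skipped <- character(0)
    for (f in remaining) {
      fit <- .olsFit(x[, c(selected, f), drop = FALSE], y)
      if (fit$rank < fit$p) {
        skipped <- c(skipped, f)
        next
      }
      if (fit$rss < bestRss - 1e-12) {
        bestRss <- fit$rss
        best <- f
      }
    }
    if (is.null(best)) {
      if (length(skipped))
        warning("all remaining candidates singular; stopping at ",
                length(selected), " features")
      break
    }
    if (length(skipped))
      warning("skipped collinear candidate(s): ",
              paste(skipped, collapse = ", "))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, c(best, skipped))
  }
  selected
}

#' Fit a linear combined-index model on selected features
#'
#' Ordinary least squares of the 0/1 early-recurrence label on the given
#' (normalized) features, with intercept.
#'
#' @param x numeric matrix/data.frame restricted to the selected features.
#' @param y numeric 0/1 response.
#' @param normalization a [NormalizationParams-class] to store with the
#'   model (identity if omitted).
#' @param pool candidate pool label to record.
#' @param cutoff risk cutoff to store (default the published 0.501; see
#'   [trainIndexModel()] for data-driven cutoffs).
#' @return a [LinearIndexModel-class].
#' @export
fitLinearIndex <- function(x, y, normalization = NULL, pool = "combined",
                           cutoff = 0.501) {
  x <- .asFeatureMatrix(x)
  stopifnot(length(y) == nrow(x))
  if (nrow(x) <= ncol(x) + 1)
    stop("need more samples than features + 1")
  X1 <- cbind(1, x)
  qrX <- qr(X1)
  if (qrX$rank < ncol(X1)) {
    bad <- colnames(X1)[qrX$pivot[seq(qrX$rank + 1, ncol(X1))]]
    stop("singular design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- .olsFit(x, y)
  if (is.null(normalization))
    normalization <- new("NormalizationParams",
                         min = stats::setNames(numeric(0), character(0)),
                         max = stats::setNames(numeric(0), character(0)))
  new("LinearIndexModel", featureNames = colnames(x),
      coefficients = unname(fit$coefficients),
      intercept = unname(fit$intercept),
      normalization = normalization, pool = pool, cutoff = cutoff)
}

#' Train a combined-index model from a feature table
#'
#' The full training recipe: learn min-max normalization on the table,
#' run sequential forward selection inside the requested candidate pool,
#' fit the linear index by ordinary least squares, and choose the risk
#' cutoff maximizing Youden's J on the training ROC (the published 0.501
#' cutoff applies to the shipped [publishedCombinedModel()], not to
#' retrained models).
#'
#' @param x feature table (samples x features), raw scale.
#' @param y 0/1 early-recurrence labels.
#' @param pool candidate pool (see [featurePool()]).
#' @param kMax number of features; defaults to [defaultPoolSize()] of the
#'   pool (18 for `"combined"`).
#' @param taxonomy a [featureTaxonomy()] object (defines pool membership
#'   and tie-break order).
#' @return a [LinearIndexModel-class] with its normalization and cutoff.
#' @export
trainIndexModel <- function(x, y, pool = "combined", kMax = NULL,
                            taxonomy = featureTaxonomy()) {
  x <- .asFeatureMatrix(x)
  if (is.null(kMax)) kMax <- defaultPoolSize(pool)
  kMax <- min(kMax, nrow(x) - 2L)
  poolNames <- intersect(featurePool(taxonomy, pool), colnames(x))
  norm <- fitNormalization(x)
  xn <- applyNormalization(x, norm)
  sel <- sequentialForwardSelection(xn, y, kMax, pool = poolNames)
  model <- fitLinearIndex(xn[, sel, drop = FALSE], y,
                          normalization = norm, pool = pool)
  scores <- drop(cbind(1, xn[, sel, drop = FALSE]) %*%
                   c(model@intercept, model@coefficients))
  if (length(unique(y)) == 2)
    model@cutoff <- rocAuc(scores, y)$cutoff
  model
}

#' Leave-one-out cross-validated combined-index predictions
#'
#' Fits exactly `n` fold models, each on the table with one sample held
#' out, and predicts the held-out sample's index from the model that
#' excluded it. Min-max normalization is re-learned inside every fold
#' (held-out values outside the fold's range are clipped). Two modes:
#' `"fixed"` (default) selects the feature subset once on the full table
#' and refits only the coefficients per fold, mirroring the usual
#' description of the procedure; `"nested"` redoes the selection inside
#' every fold and is free of selection leakage.
#'
#' @param x raw feature table (samples x features).
#' @param y 0/1 labels.
#' @param pool candidate pool.
#' @param kMax features per model (default [defaultPoolSize()]).
#' @param mode `"fixed"` or `"nested"`.
#' @param taxonomy a [featureTaxonomy()] object.
#' @return numeric vector of `n` out-of-fold predicted indices (named by
#'   row names of `x`), with attributes `nFolds` (= n) and
#'   `selected` (the fixed-mode selection, or per-fold list).
#' @export
loocvPredict <- function(x, y, pool = "combined", kMax = NULL,
                         mode = c("fixed", "nested"),
                         taxonomy = featureTaxonomy()) {
  mode <- match.arg(mode)
  x <- .asFeatureMatrix(x)
  n <- nrow(x)
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 samples")
  stopifnot(length(y) == n)
  if (is.null(kMax)) kMax <- defaultPoolSize(pool)
  kMax <- min(kMax, n - 2L)
  poolNames <- intersect(featurePool(taxonomy, pool), colnames(x))
  if (length(poolNames) == 0) poolNames <- colnames(x)
  selFixed <- NULL
  if (mode == "fixed") {
    xnFull <- applyNormalization(x, fitNormalization(x))
    selFixed <- suppressWarnings(
      sequentialForwardSelection(xnFull, y, kMax, pool = poolNames))
  }
  preds <- stats::setNames(numeric(n), rownames(x))
  selections <- vector("list", n)
  nFitted <- 0L
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]; yt <- y[-i]
    norm <- fitNormalization(xt)
    xn <- applyNormalization(xt, norm)
    sel <- if (mode == "fixed") selFixed else
      suppressWarnings(sequentialForwardSelection(xn, yt, kMax,
                                                  pool = poolNames))
    fit <- .olsFit(xn[, sel, drop = FALSE], yt)
    nFitted <- nFitted + 1L
    xv <- applyNormalization(x[i, , drop = FALSE], norm)
    preds[i] <- fit$intercept +
      sum(fit$coefficients * xv[1, sel])
    selections[[i]] <- sel
  }
  attr(preds, "nFolds") <- nFitted
  attr(preds, "selected") <- if (mode == "fixed") selFixed else selections
  preds
}
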