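# Scoring, risk classification and model serialization.

#' Score the combined index and classify recurrence risk
#'
#' The combined index of a sample is
#' `intercept + sum(coefficients * normalized features)` under the
#' model's stored normalization; risk is `"high"` iff the index is
#' strictly greater than the cutoff (an index exactly at the cutoff is
#' low risk).
#'
#' @param features named numeric vector, or matrix/data.frame with
#'   samples in rows; must contain every model feature.
#' @param model a [LinearIndexModel-class].
#' @return numeric vector of indices (one per sample).
#' @seealso [classifyRisk()], [publishedCombinedModel()]
#' @export
scoreIndex <- function(features, model) {
  stopifnot(is(model, "LinearIndexModel"))
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  features <- .asFeatureMatrix(features)
  missing <- setdiff(model@featureNames, colnames(features))
  if (length(missing))
    stop("missing model features: ", paste(missing, collapse = ", "))
  xn <- applyNormalization(features, model@normalization)
  xn <- xn[, model@featureNames, drop = FALSE]
  drop(model@intercept + xn %*% model@coefficients)
}

#' @rdname scoreIndex
#' @param index numeric vector of combined-index values.
#' @param threshold a [riskThreshold()] (default the published 0.501).
#' @return `classifyRisk`: factor with levels `"low"`, `"high"`.
#' @export
classifyRisk <- function(index, threshold = riskThreshold()) {
  stopifnot(inherits(threshold, "RiskThreshold"))
  factor(ifelse(index > threshold$cutoff, "high", "low"),
         levels = c("low", "high"))
}

#' Write / read a combined-index model as JSON
#'
#' @param model a [LinearIndexModel-class].
#' @param path file path for the JSON model.
#' @return `writeIndexModel` returns `path` invisibly; `readIndexModel`
#'   returns the model.
#' @export
writeIndexModel <- function(model, path) {
  stopifnot(is(model, "LinearIndexModel"))
  obj <- list(
    feature_names = model@featureNames,
    coefficients = model@coefficients,
    intercept = model@intercept,
    normalization = if (length(model@normalization@min) == 0) NULL else
      list(min = as.list(model@normalization@min),
           max = as.list(model@normalization@max)),
    pool = model@pool,
    cutoff = model@cutoff
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeIndexModel
#' @export
readIndexModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- if (is.null(obj$normalization))
    new("NormalizationParams", min = stats::setNames(numeric(0), character(0)),
        max = stats::setNames(numeric(0), character(0)))
  else
    new("NormalizationParams",
        min = unlist(obj$normalization$min),
        max = unlist(obj$normalization$max))
  new("LinearIndexModel",
      featureNames = as.character(obj$feature_names),
      coefficients = as.numeric(obj$coefficients),
      intercept = as.numeric(obj$intercept),
      normalization = norm,
      pool = as.character(obj$pool),
      cutoff = as.numeric(obj$cutoff))
}
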