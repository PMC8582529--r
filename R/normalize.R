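# Min-max feature normalization.

#' Learn per-feature min-max normalization bounds
#'
#' @param x numeric matrix or data.frame, samples in rows, features in
#'   columns (no missing values).
#' @return a [NormalizationParams-class] object.
#' @export
fitNormalization <- function(x) {
  x <- .asFeatureMatrix(x)
  new("NormalizationParams",
      min = apply(x, 2, min),
      max = apply(x, 2, max))
}

#' Apply min-max normalization
#'
#' Maps each feature to `(x - min) / (max - min)`. Constant features
#' (min = max) map to 0; values outside the learned range are clipped to
#' [0, 1], so normalized tables are always within the unit interval.
#'
#' @param x numeric matrix or data.frame covering the features in
#'   `params` (extra columns are ignored).
#' @param params a [NormalizationParams-class] from [fitNormalization()].
#'   Zero-length params denote identity normalization and return the
#'   input unchanged.
#' @return numeric matrix over the `params` features, values in [0, 1].
#' @export
applyNormalization <- function(x, params) {
  stopifnot(is(params, "NormalizationParams"))
  x <- .asFeatureMatrix(x)
  nms <- names(params@min)
  if (length(nms) == 0) return(x)
  missing <- setdiff(nms, colnames(x))
  if (length(missing))
    stop("features absent from table: ", paste(missing, collapse = ", "))
  x <- x[, nms, drop = FALSE]
  rng <- params@max - params@min
  out <- sweep(x, 2, params@min, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, 0), 1)
}

.asFeatureMatrix <- function(x) {
  if (is.data.frame(x)) {
    bad <- !vapply(x, is.numeric, TRUE)
    if (any(bad))
      stop("non-numeric feature columns: ",
           paste(names(x)[bad], collapse = ", "))
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                   dimnames = list(NULL, "feature"))
  if (!is.numeric(x)) stop("feature table must be numeric")
  if (anyNA(x)) stop("feature table must not contain missing values")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}
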