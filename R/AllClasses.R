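#' @import methods
NULL

#' SyntheticSample: a simulated two-channel SHG/TPEF acquisition
#'
#' Container for one synthetic sample: the SHG (collagen) and TPEF (cell
#' background) intensity channels, the three disjoint region masks
#' (portal, septal, fibrillar) and the ground-truth fiber table used to
#' validate downstream morphometry.
#'
#' @slot shg numeric matrix, non-negative SHG intensities.
#' @slot tpef numeric matrix, same shape as `shg`.
#' @slot regionMasks named list of three logical matrices
#'   (`portal`, `septal`, `fibrillar`), pairwise disjoint.
#' @slot truthFibers data.frame with one row per planted structure:
#'   `id`, `region`, `pattern` ("aggregated"/"distributed"), `length_um`,
#'   `width_um`, `orientation_deg`, `area_px`, and a list-column
#'   `centerline` of (row, col) pixel matrices.
#' @slot pixelSizeUm numeric scalar, micrometers per pixel.
#'
#' @aliases SyntheticSample
#' @exportClass SyntheticSample
setClass("SyntheticSample",
  representation(
    shg = "matrix",
    tpef = "matrix",
    regionMasks = "list",
    truthFibers = "data.frame",
    pixelSizeUm = "numeric"
  )
)

setValidity("SyntheticSample", function(object) {
  msg <- character(0)
  if (!identical(dim(object@shg), dim(object@tpef)))
    msg <- c(msg, "shg and tpef must have identical dimensions")
  if (any(object@shg < 0) || any(object@tpef < 0))
    msg <- c(msg, "channel intensities must be non-negative")
  rm <- object@regionMasks
  if (!identical(sort(names(rm)), sort(c("portal", "septal", "fibrillar"))))
    msg <- c(msg, "regionMasks must be named portal, septal, fibrillar")
  else {
    for (nm in names(rm))
      if (!identical(dim(rm[[nm]]), dim(object@shg)))
        msg <- c(msg, sprintf("region mask '%s' dimension mismatch", nm))
    if (length(msg) == 0) {
      overlap <- (rm$portal + rm$septal + rm$fibrillar)
      if (any(overlap > 1))
        msg <- c(msg, "region masks must be pairwise disjoint")
    }
  }
  if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' FeatureTaxonomy: the canonical 100 + 76 collagen feature grid
#'
#' Ordered names of the 100 morphological features (area percentages and
#' per-cell string summaries over the overlap/portal/septal/fibrillar
#' regions and all/aggregated/distributed patterns) and the 76 relativistic
#' features, each the ratio of two morphological features.
#'
#' @slot morphological character(100), morphological feature names.
#' @slot relativistic character(76), ratio feature names ("num/den").
#' @slot ratioNum character(76), numerator morphological name per ratio.
#' @slot ratioDen character(76), denominator morphological name per ratio.
#'
#' @aliases FeatureTaxonomy
#' @exportClass FeatureTaxonomy
setClass("FeatureTaxonomy",
  representation(
    morphological = "character",
    relativistic = "character",
    ratioNum = "character",
    ratioDen = "character"
  )
)

setValidity("FeatureTaxonomy", function(object) {
  msg <- character(0)
  if (length(object@morphological) != 100)
    msg <- c(msg, "exactly 100 morphological features required")
  if (length(object@relativistic) != 76)
    msg <- c(msg, "exactly 76 relativistic features required")
  all_names <- c(object@morphological, object@relativistic)
  if (anyDuplicated(all_names))
    msg <- c(msg, "feature names must be unique")
  if (length(object@ratioNum) != length(object@relativistic) ||
      length(object@ratioDen) != length(object@relativistic))
    msg <- c(msg, "ratioNum/ratioDen must parallel relativistic names")
  if (!all(object@ratioNum %in% object@morphological) ||
      !all(object@ratioDen %in% object@morphological))
    msg <- c(msg, "ratio members must be morphological feature names")
  missing <- setdiff(.publishedFeatureNames(), all_names)
  if (length(missing))
    msg <- c(msg, paste("published model features missing from taxonomy:",
                        paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' NormalizationParams: per-feature min-max bounds
#'
#' @slot min named numeric, per-feature minima learned from a training table.
#' @slot max named numeric, per-feature maxima.
#'
#' @aliases NormalizationParams
#' @exportClass NormalizationParams
setClass("NormalizationParams",
  representation(min = "numeric", max = "numeric")
)

setValidity("NormalizationParams", function(object) {
  msg <- character(0)
  if (!identical(names(object@min), names(object@max)))
    msg <- c(msg, "min and max must cover the same named features")
  if (any(object@min > object@max))
    msg <- c(msg, "min must not exceed max for any feature")
  if (length(msg)) msg else TRUE
})

#' LinearIndexModel: a linear combined-index risk model
#'
#' An ordinary least-squares model of the 0/1 early-recurrence label on a
#' selected subset of min-max normalized collagen features. The combined
#' index of a patient is `intercept + sum(coefficients * features)` after
#' normalization; values above the risk cutoff flag high early-recurrence
#' risk.
#'
#' @slot featureNames character, selected feature names (selection order).
#' @slot coefficients numeric, same length as `featureNames`.
#' @slot intercept numeric scalar.
#' @slot normalization a [NormalizationParams-class] object; zero-length
#'   bounds denote identity (no) normalization.
#' @slot pool character scalar: candidate pool the model was selected from
#'   ("combined", "overlap", "portal", "septal" or "fibrillar").
#' @slot cutoff numeric scalar, risk threshold (strict `>` means high risk).
#'
#' @aliases LinearIndexModel
#' @exportClass LinearIndexModel
setClass("LinearIndexModel",
  representation(
    featureNames = "character",
    coefficients = "numeric",
    intercept = "numeric",
    normalization = "NormalizationParams",
    pool = "character",
    cutoff = "numeric"
  )
)

setValidity("LinearIndexModel", function(object) {
  msg <- character(0)
  if (length(object@coefficients) != length(object@featureNames))
    msg <- c(msg, "one coefficient per feature required")
  if (length(object@intercept) != 1)
    msg <- c(msg, "intercept must be a scalar")
  if (!object@pool %in% c("combined", "overlap", "portal", "septal",
                          "fibrillar"))
    msg <- c(msg, "unknown candidate pool")
  if (length(object@cutoff) != 1)
    msg <- c(msg, "cutoff must be a scalar")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSample", function(object) {
  d <- dim(object@shg)
  cat(sprintf("SyntheticSample: %d x %d px at %.3g um/px (%.2f x %.2f mm)\n",
              d[1], d[2], object@pixelSizeUm,
              d[1] * object@pixelSizeUm / 1000,
              d[2] * object@pixelSizeUm / 1000))
  tf <- object@truthFibers
  if (nrow(tf)) {
    tab <- table(tf$region, tf$pattern)
    cat(sprintf("  %d ground-truth structures:\n", nrow(tf)))
    print(tab)
  } else cat("  no ground-truth structures\n")
})

setMethod("show", "FeatureTaxonomy", function(object) {
  cat("FeatureTaxonomy:", length(object@morphological), "morphological +",
      length(object@relativistic), "relativistic features\n")
  cat("  morphological: ", paste(head(object@morphological, 5),
                                 collapse = ", "), ", ...\n", sep = "")
  cat("  relativistic:  ", paste(head(object@relativistic, 3),
                                 collapse = ", "), ", ...\n", sep = "")
})

setMethod("show", "LinearIndexModel", function(object) {
  cat(sprintf("LinearIndexModel (%s pool): %d features, intercept %.4g\n",
              object@pool, length(object@featureNames), object@intercept))
  cat(sprintf("  risk cutoff: index > %.4g is high risk\n", object@cutoff))
  if (length(object@normalization@min) == 0)
    cat("  normalization: identity\n")
  else
    cat(sprintf("  normalization: min-max over %d features\n",
                length(object@normalization@min)))
  k <- min(6L, length(object@featureNames))
  if (k > 0) {
    df <- data.frame(feature = object@featureNames[seq_len(k)],
                     coefficient = round(object@coefficients[seq_len(k)], 4))
    print(df, row.names = FALSE)
    if (length(object@featureNames) > k)
      cat("  ...", length(object@featureNames) - k, "more\n")
  }
})

#' @describeIn LinearIndexModel-class model coefficients, intercept first
#' @param object a `LinearIndexModel`
#' @export
setMethod("coef", "LinearIndexModel", function(object) {
  c("(Intercept)" = object@intercept,
    stats::setNames(object@coefficients, object@featureNames))
})

# ---- accessors ---------------------------------------------------------

#' @rdname accessors
#' @param x an object of the corresponding class
#' @export
shgChannel <- function(x) x@shg

#' @rdname accessors
#' @export
tpefChannel <- function(x) x@tpef

#' Accessors for fibroIndex S4 classes
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @name accessors
#' @rdname accessors
#' @export
regionMasks <- function(x) x@regionMasks

#' @rdname accessors
#' @export
truthFibers <- function(x) x@truthFibers

#' @rdname accessors
#' @export
pixelSize <- function(x) x@pixelSizeUm

#' @rdname accessors
#' @export
morphFeatureNames <- function(x) x@morphological

#' @rdname accessors
#' @export
relFeatureNames <- function(x) x@relativistic

#' @rdname accessors
#' @export
taxonomyNames <- function(x) c(x@morphological, x@relativistic)

#' @rdname accessors
#' @export
indexFeatures <- function(x) x@featureNames

#' @rdname accessors
#' @export
intercept <- function(x) x@intercept

#' @rdname accessors
#' @export
candidatePool <- function(x) x@pool

#' @rdname accessors
#' @export
riskCutoff <- function(x) x@cutoff

#' @rdname accessors
#' @export
normalization <- function(x) x@normalization
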