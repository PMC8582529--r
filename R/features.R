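# The 100-morphological + 76-relativistic feature computation.

#' Compute the 100 morphological collagen features
#'
#' Fills the canonical morphological grid from a segmented mask and its
#' extracted strings: the overlap cell (total collagen area percent `SHG`
#' plus 9 string summaries over every string) and, per region, the three
#' area-percent features (total, aggregated, distributed — percentages of
#' the imaged tissue area) plus the 9 summaries for each pattern cell.
#' Cells with no strings yield zeros.
#'
#' @param mask a `CollagenMask` from [segmentCollagen()].
#' @param strings string table from [extractStrings()] on the same mask.
#' @param taxonomy a [featureTaxonomy()] object.
#' @param thresholds a [stringThresholds()] object.
#' @return named numeric vector of length 100, in taxonomy order.
#' @export
computeMorphologicalFeatures <- function(mask, strings,
                                         taxonomy = featureTaxonomy(),
                                         thresholds = stringThresholds()) {
  stopifnot(inherits(mask, "CollagenMask"), is(taxonomy, "FeatureTaxonomy"))
  npx <- length(mask$mask)
  strings <- categorizeStrings(strings, thresholds)
  out <- stats::setNames(numeric(100), taxonomy@morphological)
  areaPct <- function(s) 100 * sum(s$areaPx) / npx
  out["SHG"] <- areaPct(strings)
  out[.SUMMARIES] <- summarizeStrings(strings)
  for (reg in names(.REGIONS)) {
    w <- .REGION_WORDS[[reg]]
    L <- .REGIONS[[reg]]
    inReg <- strings[strings$region == reg, , drop = FALSE]
    agg <- inReg[inReg$pattern == "aggregated", , drop = FALSE]
    dis <- inReg[inReg$pattern == "distributed", , drop = FALSE]
    out[w] <- areaPct(inReg)
    out[paste0(w, "AGG")] <- areaPct(agg)
    out[paste0(w, "DIS")] <- areaPct(dis)
    out[paste0(.SUMMARIES, L)] <- summarizeStrings(inReg)
    out[paste0(.SUMMARIES, L, "A")] <- summarizeStrings(agg)
    out[paste0(.SUMMARIES, L, "D")] <- summarizeStrings(dis)
  }
  out
}

#' Compute the 76 relativistic (ratio) features
#'
#' Each relativistic feature is the ratio of two morphological features
#' (for example `NoShortStr/NoLongStr` or `SeptalAGG/Septal`). A ratio
#' whose denominator is zero is reported as 0.
#'
#' @param morph named numeric vector of the 100 morphological features, or
#'   a matrix/data.frame with samples in rows and the 100 features in
#'   columns.
#' @param taxonomy a [featureTaxonomy()] object.
#' @return named numeric vector of length 76 (or a matrix with 76 columns).
#' @export
computeRelativisticFeatures <- function(morph, taxonomy = featureTaxonomy()) {
  stopifnot(is(taxonomy, "FeatureTaxonomy"))
  if (is.null(dim(morph))) {
    if (!all(taxonomy@morphological %in% names(morph)))
      stop("morph must contain all 100 morphological features")
    num <- morph[taxonomy@ratioNum]
    den <- morph[taxonomy@ratioDen]
    out <- ifelse(den == 0, 0, num / den)
    stats::setNames(as.numeric(out), taxonomy@relativistic)
  } else {
    morph <- as.matrix(morph)
    if (!all(taxonomy@morphological %in% colnames(morph)))
      stop("morph must contain all 100 morphological features")
    num <- morph[, taxonomy@ratioNum, drop = FALSE]
    den <- morph[, taxonomy@ratioDen, drop = FALSE]
    out <- ifelse(den == 0, 0, num / den)
    colnames(out) <- taxonomy@relativistic
    out
  }
}

#' Quantify collagen morphology into the full 176-feature vector
#'
#' End-to-end morphometry for one sample: segment the SHG channel,
#' extract and categorize collagen strings, and emit the complete
#' 100 morphological + 76 relativistic feature vector.
#'
#' @param sample a [SyntheticSample-class], or a bare SHG matrix.
#' @param taxonomy a [featureTaxonomy()] object.
#' @param thresholds a [stringThresholds()] object.
#' @param regionMasks region masks when `sample` is a bare matrix
#'   (taken from the sample object otherwise).
#' @param pixelSizeUm pixel size when `sample` is a bare matrix.
#' @param ... passed to [segmentCollagen()] (e.g. `method`, `k`).
#' @return named numeric vector of length 176 with attribute `strings`
#'   (the extracted string table).
#' @export
setGeneric("collagenFeatures",
           function(sample, taxonomy = featureTaxonomy(),
                    thresholds = stringThresholds(), ...)
             standardGeneric("collagenFeatures"))

#' @rdname collagenFeatures
#' @export
setMethod("collagenFeatures", "SyntheticSample",
  function(sample, taxonomy = featureTaxonomy(),
           thresholds = stringThresholds(), ...) {
    collagenFeatures(shgChannel(sample), taxonomy, thresholds,
                     regionMasks = regionMasks(sample),
                     pixelSizeUm = pixelSize(sample), ...)
  })

#' @rdname collagenFeatures
#' @export
setMethod("collagenFeatures", "matrix",
  function(sample, taxonomy = featureTaxonomy(),
           thresholds = stringThresholds(), regionMasks = NULL,
           pixelSizeUm = 1, ...) {
    mask <- segmentCollagen(sample, pixelSizeUm, ...)
    strings <- extractStrings(mask, regionMasks, thresholds)
    morph <- computeMorphologicalFeatures(mask, strings, taxonomy,
                                          thresholds)
    rel <- computeRelativisticFeatures(morph, taxonomy)
    out <- c(morph, rel)
    attr(out, "strings") <- strings
    out
  })
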