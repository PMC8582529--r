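# Collagen segmentation and pattern split.

#' String category and aggregation thresholds
#'
#' Categorization cutoffs for collagen strings. The categories (short vs
#' long, thin vs thick, aggregated vs distributed) are part of the
#' published feature scheme but their numeric cutoffs were never released;
#' these defaults are package choices, configurable everywhere. Boundary
#' values belong to the upper class (a string exactly at `longMinUm` is
#' long).
#'
#' @param longMinUm minimum length of a "long" string, micrometers
#'   (default 20).
#' @param thickMinUm minimum width of a "thick" string, micrometers
#'   (default 3).
#' @param aggregatedMinAreaUm2 minimum component area of "aggregated"
#'   collagen, square micrometers (default 300).
#' @return a list of class `StringCategoryThresholds`.
#' @export
stringThresholds <- function(longMinUm = 20, thickMinUm = 3,
                             aggregatedMinAreaUm2 = 300) {
  stopifnot(longMinUm > 0, thickMinUm > 0, aggregatedMinAreaUm2 > 0)
  structure(list(longMinUm = longMinUm, thickMinUm = thickMinUm,
                 aggregatedMinAreaUm2 = aggregatedMinAreaUm2),
            class = "StringCategoryThresholds")
}

#' Segment collagen from an SHG intensity channel
#'
#' Default method: global threshold at `mean + k * sd` of the nonzero SHG
#' intensities (pixels at or above the threshold are collagen), followed
#' by removal of connected components smaller than `minComponentPx`
#' pixels. An Otsu threshold over the full intensity range is available as
#' an alternative. The method is deliberately simple and deterministic;
#' it is adequate for synthetic imagery and pluggable for real data.
#'
#' @param shg non-negative numeric matrix (SHG channel).
#' @param pixelSizeUm micrometers per pixel.
#' @param method `"meansd"` (default) or `"otsu"`.
#' @param k multiplier on the SD for `"meansd"` (default 2).
#' @param minComponentPx minimum component size kept, pixels (default 4).
#' @return a list of class `CollagenMask` with elements `mask` (logical
#'   matrix), `pixelSizeUm`, and `areaPercent` (100 x collagen pixels /
#'   total pixels).
#' @examples
#' m <- segmentCollagen(matrix(0, 8, 8), 2)
#' m$areaPercent  # 0
#' @export
segmentCollagen <- function(shg, pixelSizeUm, method = c("meansd", "otsu"),
                            k = 2, minComponentPx = 4L) {
  method <- match.arg(method)
  if (!is.matrix(shg) || length(shg) == 0)
    stop("shg must be a non-empty numeric matrix")
  if (any(shg < 0)) stop("shg intensities must be non-negative")
  mx <- max(shg)
  if (mx > 0 && all(shg == mx)) {
    warning("all-saturated image: returning a full collagen mask")
    mask <- matrix(TRUE, nrow(shg), ncol(shg))
  } else if (mx == 0) {
    mask <- matrix(FALSE, nrow(shg), ncol(shg))
  } else if (method == "meansd") {
    nz <- shg[shg > 0]
    thr <- mean(nz) + k * (if (length(nz) > 1) stats::sd(nz) else 0)
    mask <- shg >= thr
  } else {
    thr <- EBImage::otsu(shg / mx, range = c(0, 1))
    mask <- shg / mx >= thr
  }
  if (any(mask) && minComponentPx > 1) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minComponentPx)
    mask <- matrix(lab %in% keep, nrow(shg), ncol(shg))
  }
  structure(list(mask = mask, pixelSizeUm = pixelSizeUm,
                 areaPercent = 100 * sum(mask) / length(mask)),
            class = "CollagenMask")
}

# labelled connected components (8-connectivity) of a CollagenMask
.labelComponents <- function(mask) {
  m <- if (inherits(mask, "CollagenMask")) mask$mask else mask
  lab <- EBImage::bwlabel(m)
  matrix(as.integer(lab), nrow(m), ncol(m))
}

#' Split collagen components into aggregated and distributed patterns
#'
#' Labels every connected component of the collagen mask `"aggregated"`
#' if its area is at least `aggregatedMinAreaUm2`, `"distributed"`
#' otherwise.
#'
#' @param mask a `CollagenMask` from [segmentCollagen()] (or a logical
#'   matrix, in which case `pixelSizeUm` must be supplied).
#' @param thresholds a [stringThresholds()] object.
#' @param pixelSizeUm pixel size override when `mask` is a bare matrix.
#' @return data.frame with one row per component: `component`, `areaUm2`,
#'   `pattern`.
#' @export
splitPatterns <- function(mask, thresholds = stringThresholds(),
                          pixelSizeUm = NULL) {
  px <- if (inherits(mask, "CollagenMask")) mask$pixelSizeUm else pixelSizeUm
  stopifnot(!is.null(px))
  lab <- .labelComponents(mask)
  n <- max(lab)
  if (n == 0)
    return(data.frame(component = integer(0), areaUm2 = numeric(0),
                      pattern = character(0)))
  areaPx <- tabulate(lab[lab > 0], nbins = n)
  areaUm2 <- areaPx * px^2
  data.frame(component = seq_len(n), areaUm2 = areaUm2,
             pattern = ifelse(areaUm2 >= thresholds$aggregatedMinAreaUm2,
                              "aggregated", "distributed"))
}
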