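# Canonical feature grid.
#
# Cells: the "overlap" cell pools every collagen string in the image;
# each anatomical region (portal, septal, fibrillar) contributes three
# pattern cells (all strings, aggregated only, distributed only).
# Naming convention: measurement + region letter (P/S/F; none = overlap)
# + pattern letter (A/D; none = all patterns), e.g. NoThickStrFA =
# number of thick strings, fibrillar region, aggregated pattern.

.REGIONS <- c(portal = "P", septal = "S", fibrillar = "F")
.REGION_WORDS <- c(portal = "Portal", septal = "Septal",
                   fibrillar = "Fibrillar")
.PATTERNS <- c(all = "", aggregated = "A", distributed = "D")
.SUMMARIES <- c("NoStr", "NoShortStr", "NoLongStr", "NoThinStr",
                "NoThickStr", "StrArea", "StrLength", "StrWidth",
                "StrOrientation")
# ratio templates per cell: numerator, denominator
.CELL_RATIOS <- matrix(c(
  "NoShortStr", "NoLongStr",
  "NoThinStr",  "NoThickStr",
  "StrLength",  "StrWidth",
  "NoShortStr", "NoStr",
  "NoLongStr",  "NoStr",
  "NoThinStr",  "NoStr",
  "NoThickStr", "NoStr"
), ncol = 2, byrow = TRUE)

# suffix for every (region, pattern) cell, overlap first
.cellSuffixes <- function() {
  out <- ""
  for (r in names(.REGIONS))
    for (p in names(.PATTERNS))
      out <- c(out, paste0(.REGIONS[[r]], .PATTERNS[[p]]))
  out
}

#' Construct the canonical 176-feature collagen taxonomy
#'
#' Builds the ordered list of 100 morphological and 76 relativistic
#' feature names used throughout the package. The morphological grid is:
#' 10 overlap features (total collagen area percent `SHG` plus 9 string
#' summaries) and, for each of the portal/septal/fibrillar regions, 3 area
#' features (total, aggregated `AGG`, distributed `DIS`) plus the 9 string
#' summaries for each of the all/aggregated/distributed pattern cells.
#' The 76 relativistic features are 7 within-cell ratios for each of the
#' 10 cells plus 6 regional aggregated/distributed area fractions.
#'
#' The exact feature enumeration behind the published combined-index model
#' was never released with the model constants; this grid is a documented
#' reconstruction that totals exactly 100 + 76 and resolves every feature
#' name printed with the published coefficients.
#'
#' @return a [FeatureTaxonomy-class] object.
#' @examples
#' tax <- featureTaxonomy()
#' length(morphFeatureNames(tax)) # 100
#' length(relFeatureNames(tax))   # 76
#' @export
featureTaxonomy <- function() {
  morph <- c("SHG", .SUMMARIES)              # overlap cell: 10
  for (r in names(.REGIONS)) {
    w <- .REGION_WORDS[[r]]
    L <- .REGIONS[[r]]
    morph <- c(morph, w, paste0(w, "AGG"), paste0(w, "DIS"))
    for (p in names(.PATTERNS))
      morph <- c(morph, paste0(.SUMMARIES, L, .PATTERNS[[p]]))
  }
  num <- den <- character(0)
  for (sfx in .cellSuffixes()) {
    num <- c(num, paste0(.CELL_RATIOS[, 1], sfx))
    den <- c(den, paste0(.CELL_RATIOS[, 2], sfx))
  }
  for (r in names(.REGIONS)) {
    w <- .REGION_WORDS[[r]]
    num <- c(num, paste0(w, "AGG"), paste0(w, "DIS"))
    den <- c(den, w, w)
  }
  new("FeatureTaxonomy",
      morphological = morph,
      relativistic = paste0(num, "/", den),
      ratioNum = num, ratioDen = den)
}

#' Candidate feature pools for model selection
#'
#' Returns the feature names eligible for sequential forward selection in
#' a given pool: `"combined"` is all 176 features; each regional pool
#' restricts to the features measured in that region (its area features,
#' its pattern-cell summaries and the ratios built from them); `"overlap"`
#' restricts to whole-image features.
#'
#' @param taxonomy a [FeatureTaxonomy-class] object.
#' @param pool one of `"combined"`, `"overlap"`, `"portal"`, `"septal"`,
#'   `"fibrillar"`.
#' @return character vector of feature names, in taxonomy order.
#' @export
featurePool <- function(taxonomy, pool = c("combined", "overlap", "portal",
                                           "septal", "fibrillar")) {
  pool <- match.arg(pool)
  stopifnot(is(taxonomy, "FeatureTaxonomy"))
  if (pool == "combined") return(taxonomyNames(taxonomy))
  cellOf <- function(nms) {
    # region of a morphological name under the naming convention
    reg <- rep("overlap", length(nms))
    for (r in names(.REGIONS)) {
      w <- .REGION_WORDS[[r]]
      L <- .REGIONS[[r]]
      hit <- startsWith(nms, w) |
        grepl(paste0("(", paste(.SUMMARIES, collapse = "|"), ")",
                     L, "[AD]?$"), nms)
      reg[hit] <- r
    }
    reg
  }
  mreg <- cellOf(taxonomy@morphological)
  rreg <- cellOf(taxonomy@ratioNum)   # ratio members share a cell
  c(taxonomy@morphological[mreg == pool],
    taxonomy@relativistic[rreg == pool])
}

#' Default number of features selected per candidate pool
#'
#' Mirrors the published model sizes: 18 for the combined pool and
#' 8/11/11/13 for the overlap/portal/septal/fibrillar pools.
#'
#' @param pool candidate pool name.
#' @return integer.
#' @export
defaultPoolSize <- function(pool = c("combined", "overlap", "portal",
                                     "septal", "fibrillar")) {
  pool <- match.arg(pool)
  c(combined = 18L, overlap = 8L, portal = 11L, septal = 11L,
    fibrillar = 13L)[[pool]]
}
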