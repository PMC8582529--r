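# Published combined-index model constants (18 features + intercept),
# as printed with the original model release. The training min/max used
# to normalize features were never published, so the shipped model
# carries identity normalization: it reproduces the published linear
# arithmetic exactly but cannot reproduce the study's per-patient
# indices, which would require the original tissue images.

.PUBLISHED_INTERCEPT <- 3.838

.PUBLISHED_COEFS <- c(
  "SHG"                         =  4.300,
  "StrOrientation"              =  1.280,
  "StrAreaPA"                   = -2.413,
  "StrAreaPD"                   = -1.269,
  "NoThickStrS"                 =  3.182,
  "NoThinStrSA"                 = -2.486,
  "Fibrillar"                   = -2.591,
  "NoThickStrF"                 = -1.889,
  "NoThickStrFA"                =  1.735,
  "NoShortStr/NoLongStr"        = -3.733,
  "StrLengthP/StrWidthP"        = -0.859,
  "NoThickStrPD/NoStrPD"        = -0.771,
  "NoThinStrPD/NoThickStrPD"    = -0.599,
  "SeptalAGG/Septal"            = -1.782,
  "StrLengthSD/StrWidthSD"      = -0.761,
  "NoThinStrFA/NoThickStrFA"    =  0.957,
  "NoThickStrFD/NoStrFD"        = -0.443,
  "StrLengthFD/StrWidthFD"      =  1.067
)

.publishedFeatureNames <- function() names(.PUBLISHED_COEFS)

#' The published combined-index model
#'
#' Returns the released 18-feature linear model of early hepatocellular
#' carcinoma recurrence risk: 9 morphological and 9 relativistic collagen
#' features with their published coefficients, intercept 3.838, and the
#' published risk cutoff 0.501 (index strictly greater than 0.501 flags
#' high risk of recurrence within one year of resection).
#'
#' The model ships with identity normalization because the min-max bounds
#' of the original 64-patient training table were not released. Scoring
#' therefore reproduces the published linear arithmetic on features you
#' supply on a 0-1 scale; it does not reproduce the original study's
#' per-patient index values.
#'
#' Note: the released constants label the `StrLengthSD/StrWidthSD` ratio
#' as a fibrillar-region feature, which conflicts with its own
#' S-for-septal naming convention; this package resolves the conflict in
#' favour of the printed name (septal region, distributed pattern).
#'
#' @return a [LinearIndexModel-class] with 18 features.
#' @examples
#' m <- publishedCombinedModel()
#' zero <- stats::setNames(rep(0, 18), indexFeatures(m))
#' scoreIndex(zero, m)  # the intercept, 3.838
#' @export
publishedCombinedModel <- function() {
  new("LinearIndexModel",
      featureNames = names(.PUBLISHED_COEFS),
      coefficients = unname(.PUBLISHED_COEFS),
      intercept = .PUBLISHED_INTERCEPT,
      normalization = new("NormalizationParams",
                          min = stats::setNames(numeric(0), character(0)),
                          max = stats::setNames(numeric(0), character(0))),
      pool = "combined",
      cutoff = 0.501)
}

#' Risk threshold on the combined index
#'
#' @param cutoff numeric scalar; the published value is 0.501.
#' @return a list with elements `cutoff` and `rule` ("index > cutoff is
#'   high risk"; the inequality is strict, so an index exactly at the
#'   cutoff is low risk).
#' @export
riskThreshold <- function(cutoff = 0.501) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, is.finite(cutoff))
  structure(list(cutoff = cutoff, rule = "index > cutoff is high risk"),
            class = "RiskThreshold")
}
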