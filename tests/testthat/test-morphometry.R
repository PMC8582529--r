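test_that("segmentation handles degenerate inputs by contract", {
  m0 <- segmentCollagen(matrix(0, 16, 16), 2)
  expect_false(any(m0$mask))
  expect_equal(m0$areaPercent, 0)
  expect_warning(ms <- segmentCollagen(matrix(1, 8, 8), 2), "saturated")
  expect_true(all(ms$mask))
  expect_error(segmentCollagen(matrix(numeric(0), 0, 0), 2), "non-empty")
  # binary image maps to itself (minus sub-minimum specks)
  b <- matrix(0, 20, 20); b[5:15, 8:10] <- 1
  mb <- segmentCollagen(b, 2)
  expect_identical(mb$mask, b == 1)
})

test_that("segmented area percent recovers the planted collagen fraction", {
  s <- generateSample(tinyImageParams(seed = 21L))
  mask <- segmentCollagen(shgChannel(s), pixelSize(s))
  truthPct <- 100 * sum(truthFibers(s)$area_px) / length(shgChannel(s))
  expect_lt(abs(mask$areaPercent - truthPct), 1.5)
})

test_that("pattern split obeys the area threshold with boundary to the upper class", {
  thr <- stringThresholds(aggregatedMinAreaUm2 = 300)
  m <- matrix(FALSE, 60, 60)
  m[2:21, 2:6] <- TRUE      # 100 px = 400 um2 at 2 um/px -> aggregated
  m[40:49, 40:42] <- TRUE   # 30 px = 120 um2 -> distributed
  mask <- structure(list(mask = m, pixelSizeUm = 2,
                         areaPercent = 100 * sum(m) / length(m)),
                    class = "CollagenMask")
  sp <- splitPatterns(mask, thr)
  expect_setequal(sp$pattern, c("aggregated", "distributed"))
  expect_equal(sp$pattern[sp$areaUm2 == 400], "aggregated")
  expect_equal(sp$pattern[sp$areaUm2 == 120], "distributed")
  # exactly at the threshold -> aggregated
  m2 <- matrix(FALSE, 40, 40); m2[1:15, 1:5] <- TRUE  # 75 px = 300 um2
  mask2 <- structure(list(mask = m2, pixelSizeUm = 2, areaPercent = 0),
                     class = "CollagenMask")
  expect_equal(splitPatterns(mask2, thr)$pattern, "aggregated")
})

test_that("a single rendered fiber is measured within discretization tolerance", {
  # one straight near-horizontal fiber, 60 x 4 um, 1 um/px
  D <- 96L
  # stroked segment of 56 px plus 2 px round caps: tip-to-tip 60
  pix <- fibroIndex:::.segmentPixels(18.3, 48.6, 74.3, 48.6, 4, c(D, D))
  shg <- matrix(0, D, D); shg[pix] <- 1
  mask <- segmentCollagen(shg, 1)
  st <- extractStrings(mask)
  expect_equal(nrow(st), 1)
  expect_lt(abs(st$length_um / 60 - 1), 0.10)
  expect_lt(abs(st$width_um - 4), 1)
  expect_lt(min(st$orientation_deg, 180 - st$orientation_deg), 2)
})

test_that("string extraction assigns regions by majority mask membership", {
  s <- generateSample(tinyImageParams(seed = 13L))
  mask <- segmentCollagen(shgChannel(s), pixelSize(s))
  st <- extractStrings(mask, regionMasks(s))
  tf <- truthFibers(s)
  expect_equal(nrow(st), nrow(tf))
  expect_equal(sort(table(st$region)), sort(table(tf$region)),
               ignore_attr = TRUE)
  expect_error(
    extractStrings(mask, list(portal = regionMasks(s)$portal,
                              septal = regionMasks(s)$portal,
                              fibrillar = regionMasks(s)$fibrillar)),
    "disjoint")
  expect_equal(nrow(extractStrings(
    segmentCollagen(matrix(0, 16, 16), 2))), 0)
})

test_that("string categorization uses half-open intervals at the thresholds", {
  st <- handStrings(lengths = c(30, 20, 19.99), widths = c(3, 2.99, 5))
  expect_identical(st$lengthCategory, c("long", "long", "short"))
  expect_identical(st$widthCategory, c("thick", "thin", "thick"))
})

test_that("hand-counted string summaries are exact", {
  # 5 strings: 2 long-thick, 3 short-thin
  st <- handStrings(lengths = c(30, 45, 10, 12, 8),
                    widths = c(4, 5, 1, 2, 1.5))
  s <- summarizeStrings(st)
  expect_equal(s[["NoStr"]], 5)
  expect_equal(s[["NoLongStr"]], 2)
  expect_equal(s[["NoShortStr"]], 3)
  expect_equal(s[["NoThickStr"]], 2)
  expect_equal(s[["NoThinStr"]], 3)
  expect_equal(s[["StrLength"]], mean(c(30, 45, 10, 12, 8)))
  expect_equal(s[["StrArea"]], sum(c(30, 45, 10, 12, 8) *
                                     c(4, 5, 1, 2, 1.5)))
  expect_equal(s[["StrOrientation"]], 1)  # identical angles -> anisotropy 1
})

test_that("a blank sample yields 100 zero morphological features with the printed names", {
  tax <- featureTaxonomy()
  mask <- segmentCollagen(matrix(0, 32, 32), 2)
  morph <- computeMorphologicalFeatures(mask, extractStrings(mask), tax)
  expect_length(morph, 100)
  expect_true(all(morph == 0))
  expect_true(all(c("StrAreaPA", "NoThinStrSA", "NoThickStrFD", "SHG",
                    "SeptalAGG", "Fibrillar") %in% names(morph)))
})

test_that("collagen confined to one region zeroes the other regional features", {
  s <- generateSample(tinyImageParams(
    fibersPerRegion = c(portal = 0L, septal = 4L, fibrillar = 0L),
    seed = 6L))
  fv <- collagenFeatures(s)
  tax <- featureTaxonomy()
  portalF <- grep("P($|[AD]$)|^Portal", morphFeatureNames(tax), value = TRUE)
  expect_true(all(fv[c("Portal", "PortalAGG", "PortalDIS")] == 0))
  expect_true(all(fv[c("Fibrillar", "FibrillarAGG", "FibrillarDIS")] == 0))
  expect_true(all(fv[paste0(c("NoStr", "StrArea", "StrLength"), "F")] == 0))
  expect_equal(unname(fv["Septal"]), unname(fv["SHG"]))
})

test_that("morphological feature grid satisfies the additivity invariants", {
  for (seed in c(1L, 8L)) {
    s <- generateSample(tinyImageParams(seed = seed,
                                        aggregatePatchCount = 2L,
                                        patchAreaRangeUm2 = c(450, 800)))
    fv <- collagenFeatures(s)
    for (sfx in c("", "P", "S", "F", "PA", "PD", "SA", "SD", "FA", "FD")) {
      expect_equal(fv[[paste0("NoShortStr", sfx)]] +
                     fv[[paste0("NoLongStr", sfx)]],
                   fv[[paste0("NoStr", sfx)]])
      expect_equal(fv[[paste0("NoThinStr", sfx)]] +
                     fv[[paste0("NoThickStr", sfx)]],
                   fv[[paste0("NoStr", sfx)]])
    }
    for (w in c("Portal", "Septal", "Fibrillar"))
      expect_equal(fv[[paste0(w, "AGG")]] + fv[[paste0(w, "DIS")]],
                   fv[[w]], tolerance = 1e-9)
    expect_lte(fv[["NoStrP"]] + fv[["NoStrS"]] + fv[["NoStrF"]],
               fv[["NoStr"]])
    expect_true(all(fv[c("SHG", "Portal", "Septal", "Fibrillar")] >= 0))
    expect_true(all(fv[c("SHG", "Portal", "Septal", "Fibrillar")] <= 100))
  }
})

test_that("relativistic features honour the zero-denominator convention", {
  tax <- featureTaxonomy()
  zeros <- stats::setNames(numeric(100), morphFeatureNames(tax))
  rel <- computeRelativisticFeatures(zeros, tax)
  expect_length(rel, 76)
  expect_true(all(rel == 0))
  v <- zeros
  v["SeptalAGG"] <- 4; v["Septal"] <- 10
  expect_equal(computeRelativisticFeatures(v, tax)[["SeptalAGG/Septal"]],
               0.4)
  # hand-counted overlap cell: 3 short / 2 long
  v2 <- zeros
  v2["NoShortStr"] <- 3; v2["NoLongStr"] <- 2; v2["NoStr"] <- 5
  r2 <- computeRelativisticFeatures(v2, tax)
  expect_equal(r2[["NoShortStr/NoLongStr"]], 1.5)
  expect_equal(r2[["NoLongStr/NoStr"]], 0.4)
})

test_that("full feature vectors are complete, finite and correctly typed", {
  s <- generateSample(tinyImageParams(seed = 17L))
  fv <- collagenFeatures(s)
  tax <- featureTaxonomy()
  expect_identical(names(fv), taxonomyNames(tax))
  expect_true(all(is.finite(fv)))
  counts <- fv[grep("^No", names(fv), value = TRUE)]
  counts <- counts[!grepl("/", names(counts))]
  expect_true(all(counts == round(counts) & counts >= 0))
})
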