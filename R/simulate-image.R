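# Synthetic SHG/TPEF sample generator.
#
# Geometry: one square mosaic of tilePx-sized tiles (nTiles must be a
# perfect square). The tissue is partitioned into three vertical bands
# standing in for the portal, septal and fibrillar regions; real-tissue
# region inference is proprietary upstream software and deliberately not
# emulated here. Fibers are straight thick segments; aggregated collagen
# is rendered as filled ellipses whose area clears the aggregation
# threshold.

#' Parameters for the synthetic image generator
#'
#' @param tilePx pixels per tile edge (default 512).
#' @param pixelSizeUm micrometers per pixel (default 2).
#' @param nTiles number of tiles in the square mosaic; must be a perfect
#'   square (default 25, a 5x5 mosaic).
#' @param fibersPerRegion named integer vector `c(portal=, septal=,
#'   fibrillar=)` of distributed fibers per region.
#' @param fiberLengthRangeUm length range (min, max) in micrometers.
#' @param fiberWidthRangeUm width range (min, max) in micrometers; rendered
#'   widths snap to whole pixels.
#' @param aggregatePatchCount number of aggregated patches, cycled over the
#'   three regions (default 3).
#' @param patchAreaRangeUm2 area range for aggregated patches; keep the
#'   lower end above the aggregation threshold (default 450-900).
#' @param noiseSd standard deviation of additive Gaussian intensity noise
#'   (default 0.05; fiber signal is 1.0).
#' @param seed integer seed; every random draw in [generateSample()] comes
#'   from this seed.
#' @return a validated list of class `SimImageParams`.
#' @export
simImageParams <- function(tilePx = 512L, pixelSizeUm = 2,
                           nTiles = 25L,
                           fibersPerRegion = c(portal = 8L, septal = 6L,
                                               fibrillar = 12L),
                           fiberLengthRangeUm = c(15, 80),
                           fiberWidthRangeUm = c(3, 8),
                           aggregatePatchCount = 3L,
                           patchAreaRangeUm2 = c(450, 900),
                           noiseSd = 0.05, seed = 1L) {
  p <- list(tilePx = as.integer(tilePx), pixelSizeUm = pixelSizeUm,
            nTiles = as.integer(nTiles),
            fibersPerRegion = fibersPerRegion,
            fiberLengthRangeUm = fiberLengthRangeUm,
            fiberWidthRangeUm = fiberWidthRangeUm,
            aggregatePatchCount = as.integer(aggregatePatchCount),
            patchAreaRangeUm2 = patchAreaRangeUm2,
            noiseSd = noiseSd, seed = as.integer(seed))
  if (p$tilePx <= 0 || p$pixelSizeUm <= 0 || p$nTiles <= 0)
    stop("tilePx, pixelSizeUm and nTiles must be positive")
  side <- sqrt(p$nTiles)
  if (side != round(side))
    stop("nTiles must be a perfect square (square mosaic)")
  if (!all(c("portal", "septal", "fibrillar") %in% names(p$fibersPerRegion)))
    stop("fibersPerRegion must name portal, septal and fibrillar counts")
  if (any(p$fibersPerRegion < 0)) stop("fiber counts must be non-negative")
  for (rng in list(p$fiberLengthRangeUm, p$fiberWidthRangeUm,
                   p$patchAreaRangeUm2))
    if (length(rng) != 2 || rng[1] > rng[2] || any(rng <= 0))
      stop("ranges must be positive (min, max) pairs with min <= max")
  if (p$noiseSd < 0) stop("noiseSd must be non-negative")
  tileUm <- p$tilePx * p$pixelSizeUm
  if (p$fiberLengthRangeUm[2] + p$fiberWidthRangeUm[2] > tileUm)
    stop(sprintf(
      "inconsistent geometry: fibers up to %.0f um cannot fit in a %.0f um tile",
      p$fiberLengthRangeUm[2], tileUm))
  structure(p, class = "SimImageParams")
}

# pixels covered by a thick segment; endpoints in continuous (x, y) = (col,
# row) coordinates, width in pixels. Returns (row, col) matrix.
.segmentPixels <- function(x0, y0, x1, y1, wpx, dimRC) {
  r <- wpx / 2
  cmin <- max(1L, floor(min(x0, x1) - r - 1)); cmax <- min(dimRC[2], ceiling(max(x0, x1) + r + 1))
  rmin <- max(1L, floor(min(y0, y1) - r - 1)); rmax <- min(dimRC[1], ceiling(max(y0, y1) + r + 1))
  if (cmin > cmax || rmin > rmax) return(matrix(0L, 0, 2))
  cc <- rep(cmin:cmax, each = rmax - rmin + 1)
  rr <- rep(rmin:rmax, times = cmax - cmin + 1)
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(cc)) else
    pmin(1, pmax(0, ((cc - x0) * dx + (rr - y0) * dy) / len2))
  ex <- x0 + t * dx; ey <- y0 + t * dy
  keep <- (cc - ex)^2 + (rr - ey)^2 <= r * r
  cbind(row = rr[keep], col = cc[keep])
}

# pixels covered by a filled rotated ellipse (semi-axes a >= b, px units)
.ellipsePixels <- function(xc, yc, a, b, thetaDeg, dimRC) {
  th <- thetaDeg * pi / 180
  cmin <- max(1L, floor(xc - a - 1)); cmax <- min(dimRC[2], ceiling(xc + a + 1))
  rmin <- max(1L, floor(yc - a - 1)); rmax <- min(dimRC[1], ceiling(yc + a + 1))
  cc <- rep(cmin:cmax, each = rmax - rmin + 1)
  rr <- rep(rmin:rmax, times = cmax - cmin + 1)
  u <- (cc - xc) * cos(th) + (rr - yc) * sin(th)
  v <- -(cc - xc) * sin(th) + (rr - yc) * cos(th)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rr[keep], col = cc[keep])
}

# ordered centerline pixels along a segment: one sample per pixel of the
# dominant axis, so the rounded path is a proper 8-connected chain
# (diagonal moves stay diagonal instead of degrading into staircases)
.centerlinePixels <- function(x0, y0, x1, y1) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1L)
  t <- seq(0, 1, length.out = n)
  px <- cbind(row = round(y0 + t * (y1 - y0)), col = round(x0 + t * (x1 - x0)))
  px[!duplicated(px), , drop = FALSE]
}

#' Generate one synthetic two-channel SHG/TPEF sample
#'
#' Renders seeded collagen fibers (straight thick segments) and aggregated
#' patches (filled ellipses) into an SHG intensity channel, with a smooth
#' textured TPEF companion channel that dims at collagen sites. The image
#' is partitioned into three vertical region bands (portal, septal,
#' fibrillar); every planted structure lies entirely inside its region
#' band, and structures never touch each other, so the ground-truth table
#' maps one-to-one onto connected components of the noiseless mask.
#'
#' @param params a [simImageParams()] object.
#' @return a [SyntheticSample-class].
#' @examples
#' s <- generateSample(simImageParams(tilePx = 128L, nTiles = 1L,
#'   fibersPerRegion = c(portal = 1L, septal = 1L, fibrillar = 1L),
#'   fiberLengthRangeUm = c(20, 60), aggregatePatchCount = 0L, seed = 7L))
#' nrow(truthFibers(s))
#' @export
generateSample <- function(params) {
  stopifnot(inherits(params, "SimImageParams"))
  withr::with_seed(params$seed, .generateSampleImpl(params))
}

.generateSampleImpl <- function(p) {
  D <- p$tilePx * as.integer(sqrt(p$nTiles))
  dimRC <- c(D, D)
  px <- p$pixelSizeUm
  # vertical region bands
  b1 <- floor(D / 3); b2 <- floor(2 * D / 3)
  colBand <- function(from, to) {
    m <- matrix(FALSE, D, D); m[, from:to] <- TRUE; m
  }
  masks <- list(portal = colBand(1L, b1),
                septal = colBand(b1 + 1L, b2),
                fibrillar = colBand(b2 + 1L, D))
  bandCols <- list(portal = c(1L, b1), septal = c(b1 + 1L, b2),
                   fibrillar = c(b2 + 1L, D))

  occupied <- matrix(FALSE, D, D)   # rendered pixels + 1px margin
  fiberMask <- matrix(FALSE, D, D)
  fibers <- list()

  place <- function(pixFun, tries = 200L) {
    # pixFun() draws a candidate and returns list(pixels, meta) or NULL
    for (i in seq_len(tries)) {
      cand <- pixFun()
      if (is.null(cand)) next
      pix <- cand$pixels
      if (nrow(pix) == 0) next
      idx <- pix[, 1] + (pix[, 2] - 1L) * D
      if (any(occupied[idx])) next
      return(cand)
    }
    stop("could not place structure without overlap; region too crowded")
  }
  commit <- function(pix) {
    idx <- pix[, 1] + (pix[, 2] - 1L) * D
    fiberMask[idx] <<- TRUE
    # occupy with a 2 px margin so neighbouring structures never merge
    for (dr in -2:2) for (dc in -2:2) {
      rr <- pix[, 1] + dr; cc <- pix[, 2] + dc
      ok <- rr >= 1 & rr <= D & cc >= 1 & cc <= D
      occupied[rr[ok] + (cc[ok] - 1L) * D] <<- TRUE
    }
  }

  fid <- 0L
  for (reg in c("portal", "septal", "fibrillar")) {
    n <- p$fibersPerRegion[[reg]]
    bc <- bandCols[[reg]]
    for (i in seq_len(n)) {
      lenUm <- stats::runif(1, p$fiberLengthRangeUm[1], p$fiberLengthRangeUm[2])
      wUm <- stats::runif(1, p$fiberWidthRangeUm[1], p$fiberWidthRangeUm[2])
      wpx <- max(1L, round(wUm / px))
      lenPx <- lenUm / px
      cand <- place(function() {
        th <- stats::runif(1, 0, 180) * pi / 180
        hx <- abs(cos(th)) * lenPx / 2 + wpx / 2 + 1
        hy <- abs(sin(th)) * lenPx / 2 + wpx / 2 + 1
        if (bc[2] - bc[1] + 1 < 2 * hx + 2 || D < 2 * hy + 2) return(NULL)
        xc <- stats::runif(1, bc[1] + hx + 1, bc[2] - hx - 1)
        yc <- stats::runif(1, 1 + hy + 1, D - hy - 1)
        x0 <- xc - cos(th) * lenPx / 2; x1 <- xc + cos(th) * lenPx / 2
        y0 <- yc - sin(th) * lenPx / 2; y1 <- yc + sin(th) * lenPx / 2
        # pull the stroked segment in by the cap radius so the rendered
        # tip-to-tip extent (round caps included) equals lenPx
        h <- max(0.5, lenPx / 2 - wpx / 2)
        sx0 <- xc - cos(th) * h; sx1 <- xc + cos(th) * h
        sy0 <- yc - sin(th) * h; sy1 <- yc + sin(th) * h
        list(pixels = .segmentPixels(sx0, sy0, sx1, sy1, wpx, dimRC),
             centerline = .centerlinePixels(x0, y0, x1, y1),
             orientation = (th * 180 / pi) %% 180)
      })
      commit(cand$pixels)
      fid <- fid + 1L
      fibers[[fid]] <- list(id = fid, region = reg, pattern = "distributed",
                            length_um = lenUm, width_um = wpx * px,
                            orientation_deg = cand$orientation,
                            area_px = nrow(cand$pixels),
                            centerline = cand$centerline)
    }
  }

  regs <- rep(c("portal", "septal", "fibrillar"),
              length.out = p$aggregatePatchCount)
  for (reg in regs) {
    bc <- bandCols[[reg]]
    areaUm2 <- stats::runif(1, p$patchAreaRangeUm2[1], p$patchAreaRangeUm2[2])
    areaPx <- areaUm2 / px^2
    ratio <- stats::runif(1, 1.3, 2.5)
    a <- sqrt(areaPx * ratio / pi); b <- areaPx / (pi * a)
    cand <- place(function() {
      th <- stats::runif(1, 0, 180)
      if (bc[2] - bc[1] + 1 < 2 * a + 4 || D < 2 * a + 4) return(NULL)
      xc <- stats::runif(1, bc[1] + a + 2, bc[2] - a - 2)
      yc <- stats::runif(1, a + 2, D - a - 2)
      thr <- th * pi / 180
      x0 <- xc - cos(thr) * a; x1 <- xc + cos(thr) * a
      y0 <- yc - sin(thr) * a; y1 <- yc + sin(thr) * a
      list(pixels = .ellipsePixels(xc, yc, a, b, th, dimRC),
           centerline = .centerlinePixels(x0, y0, x1, y1),
           orientation = th %% 180)
    })
    commit(cand$pixels)
    fid <- fid + 1L
    fibers[[fid]] <- list(id = fid, region = reg, pattern = "aggregated",
                          length_um = 2 * a * px, width_um = 2 * b * px,
                          orientation_deg = cand$orientation,
                          area_px = nrow(cand$pixels),
                          centerline = cand$centerline)
  }

  shg <- matrix(0, D, D)
  shg[fiberMask] <- 1.0
  if (p$noiseSd > 0)
    shg <- pmax(shg + matrix(stats::rnorm(D * D, 0, p$noiseSd), D, D), 0)

  xs <- matrix(rep(seq_len(D), each = D), D, D)   # column index
  ys <- matrix(rep(seq_len(D), times = D), D, D)  # row index
  tpef <- 0.5 + 0.25 * sin(2 * pi * 3 * xs / D) * cos(2 * pi * 2 * ys / D)
  if (p$noiseSd > 0)
    tpef <- tpef + matrix(stats::rnorm(D * D, 0, p$noiseSd / 2), D, D)
  tpef[fiberMask] <- tpef[fiberMask] * 0.2   # holes at collagen sites
  tpef <- pmax(tpef, 0)

  tf <- if (fid == 0)
    data.frame(id = integer(0), region = character(0), pattern = character(0),
               length_um = numeric(0), width_um = numeric(0),
               orientation_deg = numeric(0), area_px = integer(0))
  else
    data.frame(id = vapply(fibers, `[[`, 1L, "id"),
               region = vapply(fibers, `[[`, "", "region"),
               pattern = vapply(fibers, `[[`, "", "pattern"),
               length_um = vapply(fibers, `[[`, 0, "length_um"),
               width_um = vapply(fibers, `[[`, 0, "width_um"),
               orientation_deg = vapply(fibers, `[[`, 0, "orientation_deg"),
               area_px = vapply(fibers, function(f) as.integer(f$area_px),
                                0L))
  tf$centerline <- lapply(fibers, `[[`, "centerline")

  new("SyntheticSample", shg = shg, tpef = tpef, regionMasks = masks,
      truthFibers = tf, pixelSizeUm = px)
}
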