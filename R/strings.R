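# Collagen string extraction: per-component skeleton length, width,
# orientation and region/pattern assignment.

# value of m shifted so element (r, c) holds m[r + dr, c + dc]
.nb <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# Zhang-Suen parallel thinning of a logical matrix down to a 1 px
# skeleton. The parallel scheme erodes isotropically (so the skeleton
# stays centred and the end erosion equals one maximal-disk radius, which
# the length measurement compensates); its known weakness -- it can
# break 2 px diagonal ribbons into fragments -- is repaired downstream,
# where .skeletonLongestPath bridges fragments through their closest
# pixel pairs.
.thin <- function(m) {
  m <- (m != 0) * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- .nb(m, -1, 0); p3 <- .nb(m, -1, 1); p4 <- .nb(m, 0, 1)
      p5 <- .nb(m, 1, 1);  p6 <- .nb(m, 1, 0);  p7 <- .nb(m, 1, -1)
      p8 <- .nb(m, 0, -1); p9 <- .nb(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & B >= 2 & B <= 6 & A == 1
      cond <- if (sub == 1)
        cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else
        cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# longest-path arc length (pixels) through a 1 px skeleton, by a double
# sweep of weighted graph distances (exact on tree-shaped skeletons,
# which thinning produces for simple fibers)
.skeletonLongestPath <- function(sk) {
  pos <- which(sk)
  if (length(pos) == 0) return(list(arc = 0, ends = integer(0)))
  if (length(pos) == 1) return(list(arc = 0, ends = c(pos, pos)))
  nr <- nrow(sk)
  r <- ((pos - 1L) %% nr) + 1L
  c <- ((pos - 1L) %/% nr) + 1L
  # Kulpa step weights: unbiased digital arc length for 8-connected chains
  wS <- 0.9481; wD <- 1.3408
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in list(c(0L, 1L, wS), c(1L, 0L, wS),
                   c(1L, 1L, wD), c(-1L, 1L, wD))) {
    rr <- r + off[1]; cc <- c + off[2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(sk)
    key <- rr + (cc - 1L) * nr
    j <- match(key, pos)
    hit <- ok & !is.na(j)
    from <- c(from, which(hit)); to <- c(to, j[hit])
    w <- c(w, rep(off[3], sum(hit)))
  }
  if (length(from) == 0) return(list(arc = 0, ends = c(pos[1], pos[1])))
  g <- igraph::make_empty_graph(n = length(pos), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  # defensive: should thinning ever fragment the skeleton, bridge the
  # pieces through their closest pixel pairs so the path spans the fiber
  comp <- igraph::components(g)
  while (comp$no > 1) {
    in1 <- comp$membership == 1
    d2 <- outer(r[in1], r[!in1], "-")^2 + outer(c[in1], c[!in1], "-")^2
    k <- arrayInd(which.min(d2), dim(d2))
    v1 <- which(in1)[k[1]]; v2 <- which(!in1)[k[2]]
    g <- igraph::add_edges(g, c(v1, v2), weight = sqrt(min(d2)))
    comp <- igraph::components(g)
  }
  sweep <- function(v) {
    d <- igraph::distances(g, v = v)[1, ]
    d[!is.finite(d)] <- -1
    d
  }
  d1 <- sweep(1L)
  a <- which.max(d1)
  d2 <- sweep(a)
  b <- which.max(d2)
  list(arc = max(d2), ends = c(pos[a], pos[b]))
}

# principal-axis orientation (degrees in [0, 180)) of pixel coordinates,
# measured from the +x (column) axis in image coordinates
.pixelOrientation <- function(rows, cols) {
  if (length(rows) < 2) return(0)
  x <- cols - mean(cols); y <- rows - mean(rows)
  mu20 <- mean(x * x); mu02 <- mean(y * y); mu11 <- mean(x * y)
  th <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  th %% 180
}

#' Extract collagen strings from a segmented mask
#'
#' Measures every connected component of the collagen mask as one
#' "string": length as the larger of (a) the skeleton longest-path arc
#' length (Kulpa step weights, which debias 8-connected chain lengths)
#' plus the boundary distance at the two skeleton endpoints (thinning
#' stops one maximal-disk radius short of each tip) and (b) the pixel
#' extent along the principal axis, which is exact for straight
#' structures; width as component area divided by that length
#' (exact for pixel ribbons of any width, where the distance transform
#' is ambiguous), floored at one pixel; orientation as the
#' principal-axis angle of the component pixels folded into [0, 180).
#' The region label is the region holding the majority of the component's
#' pixels; components outside every region mask are labelled `"none"` and
#' count only toward the whole-image (overlap) features.
#'
#' @param mask a `CollagenMask` from [segmentCollagen()].
#' @param regionMasks named list of disjoint logical matrices (`portal`,
#'   `septal`, `fibrillar`), or `NULL` to label all strings `"none"`.
#' @param thresholds a [stringThresholds()] object (drives the
#'   aggregated/distributed pattern split).
#' @return data.frame with one row per string: `component`, `length_um`,
#'   `width_um`, `orientation_deg`, `area_um2`, `areaPx`, `region`,
#'   `pattern`.
#' @export
extractStrings <- function(mask, regionMasks = NULL,
                           thresholds = stringThresholds()) {
  stopifnot(inherits(mask, "CollagenMask"))
  px <- mask$pixelSizeUm
  lab <- .labelComponents(mask)
  n <- max(lab)
  empty <- data.frame(component = integer(0), length_um = numeric(0),
                      width_um = numeric(0), orientation_deg = numeric(0),
                      area_um2 = numeric(0), areaPx = integer(0),
                      region = character(0), pattern = character(0))
  if (n == 0) return(empty)
  if (!is.null(regionMasks)) {
    stopifnot(all(c("portal", "septal", "fibrillar") %in% names(regionMasks)))
    ov <- regionMasks$portal + regionMasks$septal + regionMasks$fibrillar
    if (any(ov > 1)) stop("region masks must be pairwise disjoint")
  }
  pat <- splitPatterns(mask, thresholds)
  nr <- nrow(lab)
  idxByComp <- split(which(lab > 0), lab[lab > 0])
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- idxByComp[[as.character(i)]]
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    # component submatrix padded by one background pixel
    r0 <- min(r); c0 <- min(c)
    sub <- matrix(FALSE, max(r) - r0 + 3L, max(c) - c0 + 3L)
    sub[cbind(r - r0 + 2L, c - c0 + 2L)] <- TRUE
    sk <- .thin(sub)
    dm <- EBImage::distmap(sub * 1)
    lp <- .skeletonLongestPath(sk)
    # end-cap compensation: thinning stops one maximal-disk radius short
    # of each tip, so the tip-to-tip length is the skeleton arc plus the
    # boundary distance at both skeleton endpoints. For near-straight
    # components that estimate is cross-checked against the pixel extent
    # along the principal axis (exact for straight fibers, where
    # thinning artefacts can shorten the skeleton path); the larger of
    # the two is reported.
    capPx <- if (length(lp$ends)) sum(dm[lp$ends]) else 0
    ori <- .pixelOrientation(r, c)
    proj <- c * cos(ori * pi / 180) + r * sin(ori * pi / 180)
    extentPx <- diff(range(proj)) + 1
    lenPx <- max(lp$arc + capPx, extentPx, 1)
    # width from the area budget: exact for ribbons of any pixel width
    # (the distance transform cannot tell 1 px from 2 px ribbons apart)
    wpx <- max(1, length(idx) / lenPx)
    widthUm <- wpx * px
    lengthUm <- max(lenPx * px, widthUm)
    region <- "none"
    if (!is.null(regionMasks)) {
      hits <- vapply(c("portal", "septal", "fibrillar"),
                     function(rn) sum(regionMasks[[rn]][idx]), 0)
      if (any(hits > 0)) region <- names(hits)[which.max(hits)]
    }
    rows[[i]] <- data.frame(component = i, length_um = lengthUm,
                            width_um = widthUm,
                            orientation_deg = ori,
                            area_um2 = length(idx) * px^2,
                            areaPx = length(idx), region = region,
                            pattern = pat$pattern[i])
  }
  do.call(rbind, rows)
}

#' Categorize strings as short/long and thin/thick
#'
#' Adds `lengthCategory` and `widthCategory` columns: a string is long iff
#' `length_um >= longMinUm` and thick iff `width_um >= thickMinUm`
#' (boundary values go to the upper class). Counts are additive by
#' construction: short + long = thin + thick = total in every cell.
#'
#' @param strings data.frame from [extractStrings()].
#' @param thresholds a [stringThresholds()] object.
#' @return the input with the two category columns appended.
#' @export
categorizeStrings <- function(strings, thresholds = stringThresholds()) {
  strings$lengthCategory <- ifelse(strings$length_um >= thresholds$longMinUm,
                                   "long", "short")
  strings$widthCategory <- ifelse(strings$width_um >= thresholds$thickMinUm,
                                  "thick", "thin")
  strings
}

#' Nine string summaries for a set of strings
#'
#' Computes the per-cell summary block used by the morphological feature
#' grid: string count, short/long and thin/thick counts, total string area
#' (square micrometers), mean length and width (micrometers), and the
#' orientation anisotropy (circular resultant length of doubled angles,
#' in [0, 1]; 1 = perfectly aligned, 0 = isotropic). An empty set yields
#' all zeros.
#'
#' @param strings a categorized string data.frame
#'   (see [categorizeStrings()]), possibly zero rows.
#' @return named numeric vector of length 9 (`NoStr`, `NoShortStr`,
#'   `NoLongStr`, `NoThinStr`, `NoThickStr`, `StrArea`, `StrLength`,
#'   `StrWidth`, `StrOrientation`).
#' @export
summarizeStrings <- function(strings) {
  out <- stats::setNames(numeric(length(.SUMMARIES)), .SUMMARIES)
  if (nrow(strings) == 0) return(out)
  stopifnot(all(c("lengthCategory", "widthCategory") %in% names(strings)))
  th2 <- 2 * strings$orientation_deg * pi / 180
  out["NoStr"] <- nrow(strings)
  out["NoShortStr"] <- sum(strings$lengthCategory == "short")
  out["NoLongStr"] <- sum(strings$lengthCategory == "long")
  out["NoThinStr"] <- sum(strings$widthCategory == "thin")
  out["NoThickStr"] <- sum(strings$widthCategory == "thick")
  out["StrArea"] <- sum(strings$area_um2)
  out["StrLength"] <- mean(strings$length_um)
  out["StrWidth"] <- mean(strings$width_um)
  out["StrOrientation"] <- sqrt(mean(cos(th2))^2 + mean(sin(th2))^2)
  out
}
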