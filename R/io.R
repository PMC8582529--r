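# File formats: two-page TIFF + JSON sidecar for synthetic samples,
# CSV for feature tables and cohort records.

.rleEncode <- function(mask) {
  r <- rle(as.logical(mask))
  list(dim = dim(mask), lengths = r$lengths, values = r$values)
}

.rleDecode <- function(obj) {
  v <- inverse.rle(structure(list(lengths = as.integer(obj$lengths),
                                  values = as.logical(obj$values)),
                             class = "rle"))
  matrix(v, obj$dim[1], obj$dim[2])
}

#' Write / read a synthetic sample as TIFF + JSON sidecar
#'
#' The image is a two-page TIFF (page 1 SHG, page 2 TPEF, 32-bit float);
#' the sidecar (same path with `.json` appended) stores the pixel size,
#' run-length-encoded region masks and the ground-truth fiber table.
#'
#' @param sample a [SyntheticSample-class].
#' @param path TIFF file path.
#' @return `writeSample` returns `path` invisibly; `readSample` returns
#'   the reconstructed [SyntheticSample-class].
#' @export
writeSample <- function(sample, path) {
  stopifnot(is(sample, "SyntheticSample"))
  # TIFF storage is [0, 1]; keep per-channel scale in the sidecar
  sc <- c(shg = max(1, max(shgChannel(sample))),
          tpef = max(1, max(tpefChannel(sample))))
  tiff::writeTIFF(list(shgChannel(sample) / sc[["shg"]],
                       tpefChannel(sample) / sc[["tpef"]]),
                  path, bits.per.sample = 32)
  tf <- truthFibers(sample)
  side <- list(
    channel_scales = as.list(sc),
    pixel_size_um = pixelSize(sample),
    region_masks = lapply(regionMasks(sample), .rleEncode),
    truth_fibers = list(
      table = tf[, setdiff(names(tf), "centerline"), drop = FALSE],
      centerlines = lapply(tf$centerline, function(m)
        list(row = m[, 1], col = m[, 2]))
    ))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSample
#' @export
readSample <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == 2)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tf <- as.data.frame(side$truth_fibers$table)
  cl <- side$truth_fibers$centerlines
  tf$centerline <- if (length(cl))
    lapply(seq_along(cl$row), function(i)
      cbind(row = cl$row[[i]], col = cl$col[[i]]))
  else list()
  sc <- side$channel_scales
  new("SyntheticSample",
      shg = pages[[1]] * sc$shg, tpef = pages[[2]] * sc$tpef,
      regionMasks = lapply(side$region_masks, .rleDecode),
      truthFibers = tf,
      pixelSizeUm = side$pixel_size_um)
}

#' Write / read a feature table as CSV
#'
#' One row per sample, a `sample_id` column followed by the 176 taxonomy
#' features in order (feature names contain `/` and are preserved
#' verbatim).
#'
#' @param features numeric matrix, samples in rows (rownames = ids).
#' @param path CSV path.
#' @return `writeFeaturesCSV` returns `path` invisibly; `readFeaturesCSV`
#'   returns the matrix with sample ids as rownames.
#' @export
writeFeaturesCSV <- function(features, path) {
  df <- data.frame(sample_id = rownames(features), check.names = FALSE)
  df <- cbind(df, as.data.frame(features, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeaturesCSV
#' @export
readFeaturesCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Write / read cohort outcome records as CSV
#'
#' @param records data.frame of patient records (see [cohortRecords()]).
#' @param path CSV path.
#' @export
writeCohortCSV <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
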