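#' Construct an ImageStack
#'
#' @param frames numeric array H x W x T (single channel) or H x W x T x C.
#'   A plain H x W matrix is promoted to a single-frame stack.
#' @param pixelSizeUm micrometres per pixel (default 0.18).
#' @param frameIntervalMin minutes between frames (default 10).
#' @param channelNames optional channel names; defaults to "TL" for a single
#'   channel (transmitted light) or "ch1", "ch2", ... otherwise.
#' @return An \linkS4class{ImageStack}.
#' @export
imageStack <- function(frames, pixelSizeUm = 0.18, frameIntervalMin = 10,
                       channelNames = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  d <- dim(frames)
  nc <- if (length(d) == 4L) d[4L] else 1L
  if (is.null(channelNames))
    channelNames <- if (nc == 1L) "TL" else paste0("ch", seq_len(nc))
  new("ImageStack", frames = frames, pixelSizeUm = pixelSizeUm,
      frameIntervalMin = frameIntervalMin, channelNames = channelNames)
}

#' Construct a LabelStack
#'
#' @param labels integer array H x W x T; 0 is background. A matrix is
#'   promoted to a single frame.
#' @param pixelSizeUm micrometres per pixel.
#' @param frameIntervalMin minutes between frames.
#' @return A \linkS4class{LabelStack}.
#' @export
labelStack <- function(labels, pixelSizeUm = 0.18, frameIntervalMin = 10) {
  if (is.matrix(labels)) labels <- array(labels, c(dim(labels), 1L))
  storage.mode(labels) <- "integer"
  new("LabelStack", labels = labels, pixelSizeUm = pixelSizeUm,
      frameIntervalMin = frameIntervalMin)
}

#' Read a multi-page TIFF timelapse
#'
#' Pages are taken in file order as acquisition order. For multi-channel
#' acquisitions pass \code{channels}: pages are then interpreted frame-major
#' with the channel index varying fastest (frame1/ch1, frame1/ch2,
#' frame2/ch1, ...). Calibration is not read from TIFF metadata; supply it
#' here (or via your \linkS4class{PipelineConfig}).
#'
#' @param path TIFF file.
#' @param channels number of interleaved channels (default 1).
#' @param pixelSizeUm,frameIntervalMin physical calibration.
#' @param channelNames optional channel names.
#' @return An \linkS4class{ImageStack}. No partial stack is returned on a
#'   malformed file.
#' @export
readImageStack <- function(path, channels = 1L, pixelSizeUm = 0.18,
                           frameIntervalMin = 10, channelNames = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("cannot read TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!length(pages)) stop("TIFF '", path, "' contains no pages")
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra samples per pixel
    p
  })
  d1 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("TIFF pages have inconsistent shapes")
  channels <- as.integer(channels)
  if (length(pages) %% channels != 0L)
    stop("page count ", length(pages), " is not a multiple of ", channels,
         " channel(s)")
  nt <- length(pages) %/% channels
  a <- array(0, c(d1[1L], d1[2L], nt, channels))
  for (t in seq_len(nt)) for (c in seq_len(channels))
    a[, , t, c] <- pages[[(t - 1L) * channels + c]]
  if (channels == 1L) a <- array(a, c(d1[1L], d1[2L], nt))
  imageStack(a, pixelSizeUm = pixelSizeUm,
             frameIntervalMin = frameIntervalMin, channelNames = channelNames)
}

#' Write an ImageStack as multi-page TIFF
#'
#' Intensities are clipped to [0, 1] and written as 16-bit pages; channels
#' are interleaved frame-major (see \code{\link{readImageStack}}).
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@frames)
  nc <- if (length(d) == 4L) d[4L] else 1L
  pages <- vector("list", d[3L] * nc)
  k <- 1L
  for (t in seq_len(d[3L])) for (c in seq_len(nc)) {
    pg <- if (nc == 1L) stack@frames[, , t] else stack@frames[, , t, c]
    pages[[k]] <- pmin(pmax(pg, 0), 1)
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Import externally produced label masks
#'
#' Adapter for masks produced outside the package (for example by a learned
#' segmenter): one multi-page 16-bit label TIFF, or a directory of
#' single-page label TIFFs taken in filename sort order. Labels are passed
#' through geometrically unchanged, only relabelled to consecutive integers
#' within each frame; downstream analysis is identical whichever segmenter
#' produced the masks.
#'
#' @param path a label TIFF or a directory of per-frame label TIFFs.
#' @param nFramesExpected optional frame count of the matching image stack;
#'   a mismatch is an alignment error.
#' @param pixelSizeUm,frameIntervalMin physical calibration.
#' @return A \linkS4class{LabelStack}.
#' @export
loadExternalMasks <- function(path, nFramesExpected = NULL,
                              pixelSizeUm = 0.18, frameIntervalMin = 10) {
  readLab <- function(f) {
    pg <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    lapply(pg, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      p
    })
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF files in directory '", path, "'")
    pages <- unlist(lapply(files, readLab), recursive = FALSE)
  } else {
    pages <- readLab(path)
  }
  d1 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("mask frames have inconsistent shapes")
  if (!is.null(nFramesExpected) && length(pages) != nFramesExpected)
    stop("mask frame count (", length(pages),
         ") does not match the image stack (", nFramesExpected, " frames)")
  a <- array(0L, c(d1[1L], d1[2L], length(pages)))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (any(p != round(p)) || any(p < 0))
      stop("mask frame ", t, " contains non-integer or negative pixel values")
    p <- as.integer(round(p))
    ids <- sort(unique(p[p > 0L]))
    if (length(ids)) {
      lut <- integer(max(ids)); lut[ids] <- seq_along(ids)
      p[p > 0L] <- lut[p[p > 0L]]
    }
    a[, , t] <- p
  }
  labelStack(a, pixelSizeUm = pixelSizeUm, frameIntervalMin = frameIntervalMin)
}

#' Write a LabelStack as 16-bit multi-page TIFF
#'
#' @param labels a \linkS4class{LabelStack}; labels must be < 65536.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeLabelStack <- function(labels, path) {
  stopifnot(is(labels, "LabelStack"))
  if (max(labels@labels) > 65535L) stop("labels exceed 16-bit range")
  pages <- lapply(seq_len(dim(labels@labels)[3L]),
                  function(t) labels@labels[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

.measurementCols <- c("frame", "label", "centroid_x_um", "centroid_y_um",
                      "area_um2", "major_um", "minor_um", "aspect_ratio",
                      "orientation_rad", "degenerate")

.validateMeasurements <- function(table) {
  miss <- setdiff(setdiff(.measurementCols, "degenerate"), names(table))
  if (length(miss))
    stop("measurement table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(table)) {
    if (any(table$aspect_ratio < 1))
      stop("invalid measurement table: aspect_ratio must be >= 1")
    if (any(table$area_um2 <= 0))
      stop("invalid measurement table: area_um2 must be > 0")
    if (any(table$major_um < table$minor_um))
      stop("invalid measurement table: major_um must be >= minor_um")
  }
  invisible(table)
}

#' Write a measurement table to CSV
#'
#' Columns are written in the fixed documented order (\code{frame, label,
#' centroid_x_um, centroid_y_um, area_um2, major_um, minor_um, aspect_ratio,
#' orientation_rad, degenerate}); values round-trip through
#' \code{\link{readMeasurements}} to better than 1e-6 relative. Tables
#' violating the measurement invariants (AR < 1, non-positive area,
#' major < minor) are refused.
#'
#' @param table a measurement data.frame from \code{\link{measureAll}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMeasurements <- function(table, path) {
  .validateMeasurements(table)
  if (!"degenerate" %in% names(table)) table$degenerate <- FALSE
  out <- table[, .measurementCols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "frame" &
    names(out) != "label"
  out[num] <- lapply(out[num], function(x) signif(x, 9))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table from CSV
#'
#' @param path CSV written by \code{\link{writeMeasurements}}.
#' @return A validated measurement data.frame.
#' @export
readMeasurements <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  .validateMeasurements(tab)
  tab
}
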