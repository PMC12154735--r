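#' Classical segmentation parameters
#'
#' Parameters of the threshold-plus-morphology segmenter used to produce
#' label masks from transmitted-light frames. This segmenter fulfils the
#' same output contract as externally produced (e.g. learned) masks imported
#' with \code{\link{loadExternalMasks}}: background 0, one connected
#' component per label, objects below the minimum area removed, holes
#' filled. Touching objects are separated only where a background (septum)
#' line survives thresholding; no watershed splitting is applied.
#'
#' @param threshold_method \code{"otsu"} (per-frame Otsu threshold) or
#'   \code{"fixed"}.
#' @param threshold_value intensity threshold when \code{"fixed"}.
#' @param min_area_um2 components smaller than this are removed (default 3).
#' @param morphology_radius_px radius of the opening element (default 1).
#' @param invert_contrast set \code{TRUE} for dark cells on bright
#'   background.
#' @param erosion_px optional fixed-width mask erosion applied after
#'   labelling (default 0, i.e. report areas as measured; masks from
#'   intensity thresholding and from learned segmenters tend to run slightly
#'   larger than the true cell outline).
#' @return A list of class \code{SegParams}.
#' @export
segParams <- function(threshold_method = c("otsu", "fixed"),
                      threshold_value = NA_real_,
                      min_area_um2 = 3.0,
                      morphology_radius_px = 1L,
                      invert_contrast = FALSE,
                      erosion_px = 0L) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && !is.finite(threshold_value))
    stop("'threshold_value' is required for threshold_method = 'fixed'")
  if (min_area_um2 <= 0) stop("'min_area_um2' must be > 0")
  structure(list(threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_area_um2 = min_area_um2,
                 morphology_radius_px = as.integer(morphology_radius_px),
                 invert_contrast = invert_contrast,
                 erosion_px = as.integer(erosion_px)),
            class = "SegParams")
}

#' Segment one frame into labelled objects
#'
#' Thresholds a single 2-D intensity frame (per-frame Otsu by default),
#' applies a morphological opening, fills holes, labels connected
#' components (8-connectivity) and removes components below the minimum
#' area. A constant-intensity frame yields an empty labelling rather than
#' an error.
#'
#' @param frame 2-D numeric matrix of finite intensities.
#' @param params a \code{\link{segParams}} list.
#' @param pixelSizeUm micrometres per pixel, used for the area filter.
#' @return Integer label matrix of the same shape; 0 is background and
#'   labels are consecutive from 1.
#' @export
segmentFrame <- function(frame, params = segParams(), pixelSizeUm = 0.18) {
  stopifnot(is.matrix(frame))
  if (any(!is.finite(frame))) stop("frame contains non-finite intensities")
  x <- frame
  if (params$invert_contrast) x <- max(x) - x
  rng <- range(x)
  if (diff(rng) < 1e-12) return(matrix(0L, nrow(frame), ncol(frame)))
  xn <- (x - rng[1]) / diff(rng)
  thr <- if (params$threshold_method == "otsu") {
    EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  } else {
    (params$threshold_value - rng[1]) / diff(rng)
  }
  bw <- xn > thr
  if (params$morphology_radius_px > 0) {
    kern <- EBImage::makeBrush(2L * params$morphology_radius_px + 1L,
                               shape = "disc")
    bw <- EBImage::opening(bw, kern)
  }
  bw <- EBImage::fillHull(bw)
  lb <- EBImage::bwlabel(bw)
  if (params$erosion_px > 0) {
    kern <- EBImage::makeBrush(2L * params$erosion_px + 1L, shape = "disc")
    lb <- lb * as.numeric(EBImage::erode(lb > 0, kern))
  }
  lm <- matrix(as.integer(round(lb)), nrow(frame), ncol(frame))
  if (max(lm) == 0L) return(lm)
  minPx <- params$min_area_um2 / pixelSizeUm^2
  cnt <- tabulate(lm[lm > 0L], nbins = max(lm))
  keep <- which(cnt >= minPx)
  lut <- integer(max(lm))
  lut[keep] <- seq_along(keep)
  lm[lm > 0L] <- lut[lm[lm > 0L]]
  lm
}

#' Segment every frame of a timelapse
#'
#' Applies \code{\link{segmentFrame}} frame by frame.
#'
#' @param stack an \linkS4class{ImageStack}; for multi-channel stacks the
#'   transmitted-light channel is selected with \code{channel}.
#' @param params a \code{\link{segParams}} list.
#' @param channel channel index to segment (default 1).
#' @return A \linkS4class{LabelStack} with the stack's calibration.
#' @export
segmentStack <- function(stack, params = segParams(), channel = 1L) {
  stopifnot(is(stack, "ImageStack"))
  nT <- nFrames(stack)
  d <- dim(stack@frames)
  lab <- array(0L, c(d[1L], d[2L], nT))
  for (t in seq_len(nT))
    lab[, , t] <- segmentFrame(getFrame(stack, t, channel), params,
                               pixelSize(stack))
  labelStack(lab, pixelSizeUm = pixelSize(stack),
             frameIntervalMin = frameInterval(stack))
}
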