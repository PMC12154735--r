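#' Partition a germinating cell into spore body and outgrowth
#'
#' Splits a cell mask into the spore body — a disc of the time-zero radius
#' placed at the round end (the pole farthest from the outgrowth tip),
#' intersected with the mask — and the outgrowth (the remainder). The
#' construction is purely geometric and rotation-invariant.
#'
#' @param px_x,px_y micrometre coordinates of the cell's mask pixels.
#' @param x0,y0 time-zero centroid of the cell (um).
#' @param r0 time-zero body radius (um), e.g. \code{sqrt(area0 / pi)}.
#' @param theta orientation of the major axis at the evaluated frame (rad).
#' @param minProtrusionUm minimum tip protrusion beyond the body disc for
#'   the cell to be partitionable (default 0.5 um).
#' @param pixelSizeUm when positive, the round-end pole is pulled back half
#'   a pixel before placing the disc: the extreme mask pixel's centre lies
#'   about half a pixel inside the continuous cell outline, which would
#'   otherwise bias the disc toward the tip.
#' @return list with logical vector \code{body} (TRUE for body pixels),
#'   \code{center} (body-disc centre, um), and \code{protrusion_um}.
#' @export
defineSporeBody <- function(px_x, px_y, x0, y0, r0, theta,
                            minProtrusionUm = 0.5, pixelSizeUm = 0) {
  ux <- cos(theta); uy <- sin(theta)
  s <- (px_x - x0) * ux + (px_y - y0) * uy
  # tip side = the pole reaching farther from the t0 centre
  tipSign <- if (max(s) >= -min(s)) 1 else -1
  pro <- max(abs(s)) - r0
  if (pro < minProtrusionUm)
    stop("cell not germinated enough to partition (protrusion ",
         sprintf("%.2f", max(pro, 0)), " um)")
  # round-end extreme pixel, then step one body radius back toward the tip
  iRe <- which.min(tipSign * s)
  rEff <- r0 - pixelSizeUm / 2
  cx <- px_x[iRe] + tipSign * ux * rEff
  cy <- px_y[iRe] + tipSign * uy * rEff
  # membership counts a pixel whose unit square overlaps the disc
  body <- (px_x - cx)^2 + (px_y - cy)^2 <= (r0 + pixelSizeUm / 2)^2
  list(body = body, center = c(cx, cy), protrusion_um = pro)
}

#' Fraction of fluorescence signal retained in the spore body
#'
#' Background-subtracted intensity sums over the body and outgrowth masks:
#' \code{fraction_in_body = sum(body, (I - bg)+) / sum(cell, (I - bg)+)},
#' negative background-subtracted pixels clamped to zero. Raw intensities
#' are used (display scaling plays no role), so the fractions are invariant
#' to any positive intensity rescaling. The two fractions sum to one
#' exactly.
#'
#' @param values raw channel intensities of the cell's mask pixels.
#' @param body logical vector: TRUE for body pixels (from
#'   \code{\link{defineSporeBody}}).
#' @param background scalar background estimate, typically the median
#'   intensity outside all cell masks in that frame.
#' @return list: \code{fraction_in_body}, \code{fraction_in_outgrowth},
#'   \code{body_px}, \code{outgrowth_px}, \code{background}.
#' @export
partitionFraction <- function(values, body, background = 0) {
  stopifnot(length(values) == length(body))
  v <- pmax(values - background, 0)
  tot <- sum(v)
  if (tot <= 0) stop("zero total signal: partition fraction is undefined")
  fb <- sum(v[body]) / tot
  list(fraction_in_body = fb, fraction_in_outgrowth = 1 - fb,
       body_px = sum(body), outgrowth_px = sum(!body),
       background = background)
}

#' Quantify vacuole partitioning at the first division
#'
#' For every gated, germinated track, measures the fraction of
#' second-channel (vacuole dye) signal retained in the spore body versus
#' the germ-tube outgrowth at the frame immediately before the first
#' division (the last frame the cell is a single object). Background is the
#' per-frame median of the channel outside all cell masks.
#'
#' @param stack a two-channel \linkS4class{ImageStack}.
#' @param labels the matching \linkS4class{LabelStack}.
#' @param trackset a \linkS4class{TrackSet} measured from \code{labels}.
#' @param calls data.frame from \code{\link{phenotypeTracks}}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param channel index of the dye channel (default 2).
#' @return data.frame: \code{track_id, frame, fraction_in_body,
#'   fraction_in_outgrowth, body_px, outgrowth_px, background}. Tracks that
#'   cannot be partitioned (no outgrowth, zero signal) are skipped with a
#'   message-level note in the \code{skipped} attribute.
#' @export
vacuolePartition <- function(stack, labels, trackset, calls,
                             config = pipelineConfig(), channel = 2L) {
  stopifnot(is(stack, "ImageStack"), is(labels, "LabelStack"))
  d <- dim(stack@frames)
  if (length(d) < 4L || d[4L] < channel)
    stop("stack has no channel ", channel)
  m <- measurements(trackset)
  H <- dim(labels@labels)[1L]
  pxsz <- pixelSize(labels)
  todo <- calls[calls$is_spore & calls$germinated &
                  !is.na(calls$division_frame), , drop = FALSE]
  out <- list(); skipped <- character(0)
  for (k in seq_len(nrow(todo))) {
    id <- todo$track_id[k]
    fe <- todo$division_frame[k] - 1L
    tr <- m[m$track_id == id & !m$interpolated, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    cand <- tr[tr$frame <= fe, , drop = FALSE]
    if (!nrow(cand)) { skipped <- c(skipped, paste(id, "no frame")); next }
    row <- cand[nrow(cand), ]
    t0row <- tr[1L, ]
    lf <- labels@labels[, , row$frame + 1L]
    idx <- which(lf == row$label)
    if (!length(idx)) { skipped <- c(skipped, paste(id, "no mask")); next }
    px_x <- (((idx - 1L) %/% H) + 0.5) * pxsz
    px_y <- (((idx - 1L) %% H) + 0.5) * pxsz
    r0 <- sqrt(t0row$area_um2 / pi)
    bd <- tryCatch(
      defineSporeBody(px_x, px_y, t0row$centroid_x_um, t0row$centroid_y_um,
                      r0, row$orientation_rad, pixelSizeUm = pxsz),
      error = function(e) NULL)
    if (is.null(bd)) { skipped <- c(skipped, paste(id, "no outgrowth")); next }
    ch2 <- stack@frames[, , row$frame + 1L, channel]
    bg <- median(ch2[lf == 0L])
    pf <- tryCatch(partitionFraction(ch2[idx], bd$body, bg),
                   error = function(e) NULL)
    if (is.null(pf)) { skipped <- c(skipped, paste(id, "no signal")); next }
    out[[length(out) + 1L]] <- data.frame(
      track_id = id, frame = row$frame,
      fraction_in_body = pf$fraction_in_body,
      fraction_in_outgrowth = pf$fraction_in_outgrowth,
      body_px = pf$body_px, outgrowth_px = pf$outgrowth_px,
      background = bg)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(track_id = integer(), frame = integer(),
               fraction_in_body = numeric(), fraction_in_outgrowth = numeric(),
               body_px = integer(), outgrowth_px = integer(),
               background = numeric())
  attr(res, "skipped") <- skipped
  res
}
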