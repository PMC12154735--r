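#' Gate circular spores at time point zero
#'
#' Unique particles with an aspect ratio strictly below the gate threshold
#' (default 1.4) at time point zero are circular and therefore likely
#' spores; they pass the gate. Particles present at frame 0 with AR at or
#' above the threshold are rejected (typically debris), and tracks absent
#' at frame 0 are rejected separately as late-appearing objects.
#'
#' @param trackset a \linkS4class{TrackSet}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with integer track-id vectors \code{gated},
#'   \code{rejected} (present at t0, AR >= threshold) and
#'   \code{absent_at_t0}.
#' @export
gateSpores <- function(trackset, config = pipelineConfig()) {
  m <- measurements(trackset)
  t0 <- m[m$frame == 0L & !m$interpolated, ]
  present <- t0$track_id
  gated <- t0$track_id[t0$aspect_ratio < config@sporeARMax]
  all_ids <- trackEvents(trackset)$track_id
  list(gated = sort(gated),
       rejected = sort(setdiff(present, gated)),
       absent_at_t0 = sort(setdiff(all_ids, present)))
}

# first frame with AR strictly above `thr`; a crossing supported only by an
# interpolated row is shifted to the next measured frame
.firstDivisionFrame <- function(frame, ar, interpolated, thr) {
  idx <- which(ar > thr)
  if (!length(idx)) return(NA_integer_)
  j <- idx[1L]
  if (interpolated[j]) {
    nxt <- which(!interpolated & seq_along(frame) > j)
    if (!length(nxt)) return(NA_integer_)
    j <- nxt[1L]
  }
  frame[j]
}

#' Call the first division of one track
#'
#' The first division (successful germination) is the time when the cell's
#' aspect ratio exceeds the division threshold (default 3.0, strict). The
#' raw per-frame series is used; if the first crossing lies on an
#' interpolated (focus-gap) row the call is shifted to the next measured
#' frame, so artifact frames cannot create divisions.
#'
#' @param frame 0-based frame indices of the track's rows.
#' @param ar aspect-ratio series.
#' @param interpolated logical flags per row (default none).
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with \code{division_frame} (0-based, \code{NA} if the
#'   threshold is never exceeded) and \code{division_time_min}
#'   (\code{frame * frameIntervalMin}).
#' @examples
#' callFirstDivision(0:4, c(1.1, 1.3, 2.0, 3.05, 3.4))
#' @export
callFirstDivision <- function(frame, ar, interpolated = rep(FALSE, length(ar)),
                              config = pipelineConfig()) {
  stopifnot(length(frame) == length(ar))
  f <- .firstDivisionFrame(frame, ar, interpolated, config@divisionAR)
  list(division_frame = f,
       division_time_min = if (is.na(f)) NA_real_ else
         f * config@frameIntervalMin)
}

# per-pole protrusion of a mask beyond the t0 spore-body disc, measured
# along the major axis through the t0 centroid
.poleProtrusions <- function(px_x, px_y, x0, y0, r0, theta) {
  ux <- cos(theta); uy <- sin(theta)
  s <- (px_x - x0) * ux + (px_y - y0) * uy
  c(plus = max(max(s) - r0, 0), minus = max(-min(s) - r0, 0))
}

#' Classify the outgrowth phenotype of one germinating spore
#'
#' Applies the five-class outgrowth taxonomy to a gated track, evaluated at
#' the frame before its first division (or its last frame when it never
#' divides). The spore body is taken as a disc of the time-zero radius at
#' the time-zero centroid; the protrusion on each side is the farthest
#' mask pixel beyond that disc along the major axis. Rules in priority
#' order: exploded (track ends with a large area drop, fragments, or
#' disappearance), bubble (a split event while still circular), bipolar
#' (both poles protrude), elongated (protrusion beyond the 6-um cutoff),
#' otherwise normal. A spore that is both bipolar and elongated is counted
#' bipolar.
#'
#' @param trackset a \linkS4class{TrackSet}.
#' @param labels the \linkS4class{LabelStack} the tracks were measured from.
#' @param trackId the track to classify.
#' @param divisionFrame its called division frame (0-based, \code{NA} if
#'   none), as returned by \code{\link{callFirstDivision}} or
#'   \code{\link{phenotypeTracks}}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with \code{phenotype} (\code{"normal"}, \code{"elongated"},
#'   \code{"bubble"}, \code{"bipolar"}, \code{"exploded"} or \code{"none"}),
#'   \code{outgrowth_length_um} (max protrusion) and \code{flagged}
#'   (\code{TRUE} when masks needed for the call were missing).
#' @export
classifyOutgrowth <- function(trackset, labels, trackId, divisionFrame = NA,
                              config = pipelineConfig()) {
  m <- measurements(trackset)
  ev <- trackEvents(trackset)
  tr <- m[m$track_id == trackId, , drop = FALSE]
  tr <- tr[order(tr$frame), , drop = FALSE]
  e <- ev[ev$track_id == trackId, ]
  lastKept <- max(m$frame)
  measured <- tr[!tr$interpolated, , drop = FALSE]
  lastRow <- measured[nrow(measured), ]

  # rule 1: exploded
  exploded <- FALSE
  if (e$terminal_event != "split" && e$end_frame < lastKept) {
    n <- nrow(measured)
    if (n >= 3L) {
      recentMax <- max(measured$area_um2[max(1L, n - 2L):(n - 1L)])
      if (lastRow$area_um2 < (1 - config@explodeAreaDropFrac) * recentMax)
        exploded <- TRUE
    }
    if (!exploded) {
      nxt <- m[m$frame > e$end_frame & m$frame <= e$end_frame + 2L &
                 !m$interpolated, ]
      if (nrow(nxt)) {
        dd <- sqrt((nxt$centroid_x_um - lastRow$centroid_x_um)^2 +
                     (nxt$centroid_y_um - lastRow$centroid_y_um)^2)
        starters <- unique(nxt$track_id[dd <= 5])
        starters <- setdiff(starters, trackId)
        newborn <- ev$track_id[ev$start_frame > e$end_frame]
        if (length(intersect(starters, newborn)) >= 3L) exploded <- TRUE
        if (length(intersect(starters, newborn)) == 0L &&
            !length(starters)) exploded <- TRUE   # disappearance
      } else {
        exploded <- TRUE                          # disappearance
      }
    }
  }
  if (exploded)
    return(list(phenotype = "exploded", outgrowth_length_um = NA_real_,
                flagged = FALSE))

  # rule 2: bubble — split while still circular
  if (e$terminal_event == "split" && lastRow$aspect_ratio < config@bubbleARMax)
    return(list(phenotype = "bubble", outgrowth_length_um = NA_real_,
                flagged = FALSE))

  if (is.na(divisionFrame))
    return(list(phenotype = "none", outgrowth_length_um = NA_real_,
                flagged = FALSE))

  # evaluation frame: the frame before division, measured
  fe <- divisionFrame - 1L
  cands <- measured[measured$frame <= fe, , drop = FALSE]
  if (!nrow(cands))
    return(list(phenotype = "none", outgrowth_length_um = NA_real_,
                flagged = TRUE))
  evalRow <- cands[nrow(cands), ]
  t0row <- measured[measured$frame == min(measured$frame), ]
  r0 <- sqrt(t0row$area_um2 / pi)
  lf <- labels@labels[, , evalRow$frame + 1L]
  idx <- which(lf == evalRow$label)
  if (!length(idx))
    return(list(phenotype = "none", outgrowth_length_um = NA_real_,
                flagged = TRUE))
  H <- dim(labels@labels)[1L]
  pxsz <- pixelSize(labels)
  px_x <- (((idx - 1L) %/% H) + 0.5) * pxsz
  px_y <- (((idx - 1L) %% H) + 0.5) * pxsz
  pro <- .poleProtrusions(px_x, px_y, t0row$centroid_x_um,
                          t0row$centroid_y_um, r0, evalRow$orientation_rad)
  outLen <- max(pro)
  pheno <- if (all(pro > config@bipolarMinProtrusionUm)) "bipolar"
  else if (outLen > config@elongatedCutoffUm) "elongated"
  else "normal"
  list(phenotype = pheno, outgrowth_length_um = outLen, flagged = FALSE)
}

#' Score germination for every track
#'
#' Orchestrates the per-track scoring: the time-zero spore gate, the
#' aspect-ratio first-division call (with the bubble split event as the
#' alternative division route for cells that divide while still circular),
#' the outgrowth phenotype, and the starting area.
#'
#' @param trackset a \linkS4class{TrackSet}.
#' @param labels the \linkS4class{LabelStack} the measurements came from
#'   (needed for the phenotype geometry; may be \code{NULL} to skip
#'   phenotype classification).
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame with one row per track: \code{track_id, present_t0,
#'   is_spore, ar_t0, starting_area_um2, germinated, division_frame,
#'   division_time_min, division_route} ("ar" or "split"), \code{phenotype,
#'   outgrowth_length_um, flagged}.
#' @export
phenotypeTracks <- function(trackset, labels = NULL,
                            config = pipelineConfig()) {
  m <- measurements(trackset)
  ev <- trackEvents(trackset)
  gate <- gateSpores(trackset, config)
  out <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    id <- ev$track_id[k]
    tr <- m[m$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    t0 <- tr[tr$frame == 0L & !tr$interpolated, ]
    present <- nrow(t0) == 1L
    isSpore <- present && id %in% gate$gated
    div <- .firstDivisionFrame(tr$frame, tr$aspect_ratio, tr$interpolated,
                               config@divisionAR)
    route <- if (!is.na(div)) "ar" else NA_character_
    if (is.na(div) && ev$terminal_event[k] == "split") {
      lastMeas <- tr[!tr$interpolated, ]
      if (lastMeas$aspect_ratio[nrow(lastMeas)] < config@bubbleARMax) {
        div <- ev$split_frame[k]
        route <- "split"
      }
    }
    pheno <- NA_character_; outLen <- NA_real_; flg <- FALSE
    if (isSpore && !is.null(labels)) {
      cl <- classifyOutgrowth(trackset, labels, id, divisionFrame = div,
                              config = config)
      pheno <- cl$phenotype; outLen <- cl$outgrowth_length_um
      flg <- cl$flagged
      if (pheno == "exploded") { div <- NA_integer_; route <- NA_character_ }
    }
    out[[k]] <- data.frame(
      track_id = id, present_t0 = present, is_spore = isSpore,
      ar_t0 = if (present) t0$aspect_ratio else NA_real_,
      starting_area_um2 = if (present) t0$area_um2 else NA_real_,
      germinated = isSpore && !is.na(div),
      division_frame = if (isSpore) div else NA_integer_,
      division_time_min = if (isSpore && !is.na(div))
        div * frameInterval(trackset) else NA_real_,
      division_route = if (isSpore) route else NA_character_,
      phenotype = pheno, outgrowth_length_um = outLen, flagged = flg,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Germination efficiency of a scored population
#'
#' The fraction of gated spores that successfully underwent a first
#' division before the end of the timelapse, over the total spores scored.
#' Populations below 50 gated spores trigger a warning (figure convention:
#' more than 50 spores per sample).
#'
#' @param calls data.frame from \code{\link{phenotypeTracks}}.
#' @param endFrame 0-based last frame counted (default: no limit).
#' @return list with \code{efficiency}, \code{n_divided}, \code{n_spores}.
#' @export
germinationEfficiency <- function(calls, endFrame = Inf) {
  g <- calls[calls$is_spore, , drop = FALSE]
  if (!nrow(g)) stop("no gated spores: germination efficiency is undefined")
  if (nrow(g) < 50L)
    warning("fewer than 50 gated spores (", nrow(g),
            "); figure convention expects N > 50 per sample")
  div <- !is.na(g$division_frame) & g$division_frame <= endFrame
  list(efficiency = sum(div) / nrow(g),
       n_divided = sum(div), n_spores = nrow(g))
}

# centered moving average with shrinking edge windows
.movAvg <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Detect the swelling window of one track
#'
#' Swelling is an increase in cell area without an increase in aspect ratio
#' (a departure from circularity has not yet begun). On the smoothed
#' series, the window is the longest run of frames whose relative area
#' slope exceeds \code{swellingAreaEps} while the absolute aspect-ratio
#' slope stays within \code{swellingAREps}; runs shorter than two slope
#' steps are ignored.
#'
#' @param frame 0-based frame indices.
#' @param area area series (um^2).
#' @param ar aspect-ratio series.
#' @param config a \linkS4class{PipelineConfig}.
#' @param divisionFrame optional: truncate the search before this frame.
#' @return \code{NULL} when no window qualifies, else list with
#'   \code{start_frame}, \code{end_frame}, \code{area_gain_fraction}.
#' @export
detectSwellingWindow <- function(frame, area, ar, config = pipelineConfig(),
                                 divisionFrame = NA) {
  stopifnot(length(frame) == length(area), length(area) == length(ar))
  if (!is.na(divisionFrame)) {
    keep <- frame < divisionFrame
    frame <- frame[keep]; area <- area[keep]; ar <- ar[keep]
  }
  n <- length(frame)
  if (n < config@smoothingWindowFrames || n < 3L) return(NULL)
  aS <- .movAvg(area, config@smoothingWindowFrames)
  rS <- .movAvg(ar, config@smoothingWindowFrames)
  relA <- diff(aS) / aS[-n]
  dAR <- diff(rS)
  ok <- relA > config@swellingAreaEps & abs(dAR) <= config@swellingAREps
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 2L)
  if (!length(runs)) return(NULL)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  list(start_frame = frame[i0], end_frame = frame[i1 + 1L],
       area_gain_fraction = area[i1 + 1L] / area[i0] - 1)
}

#' Population mean curves of area and aspect ratio
#'
#' Per-frame mean and standard error (sd/sqrt(n)) of area and aspect ratio
#' over the tracks alive at that frame. Interpolated (focus-gap) rows are
#' excluded from the means; with a single contributing track the standard
#' error is reported as 0 and n records the support.
#'
#' @param trackset a \linkS4class{TrackSet}.
#' @param trackIds optional subset of tracks (e.g. the gated spores).
#' @return data.frame: \code{frame, time_min, mean_area, se_area, mean_ar,
#'   se_ar, n}.
#' @export
populationCurves <- function(trackset, trackIds = NULL) {
  m <- measurements(trackset)
  if (!is.null(trackIds)) m <- m[m$track_id %in% trackIds, , drop = FALSE]
  m <- m[!m$interpolated, , drop = FALSE]
  if (!nrow(m)) stop("no measurements to summarize")
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  fr <- sort(unique(m$frame))
  out <- data.frame(
    frame = fr,
    time_min = fr * frameInterval(trackset),
    mean_area = vapply(fr, function(f) mean(m$area_um2[m$frame == f]),
                       numeric(1)),
    se_area = vapply(fr, function(f) sem(m$area_um2[m$frame == f]),
                     numeric(1)),
    mean_ar = vapply(fr, function(f) mean(m$aspect_ratio[m$frame == f]),
                     numeric(1)),
    se_ar = vapply(fr, function(f) sem(m$aspect_ratio[m$frame == f]),
                   numeric(1)),
    n = vapply(fr, function(f) sum(m$frame == f), integer(1)))
  out
}
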