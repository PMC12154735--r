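#' Link per-frame measurements into tracks
#'
#' Greedy nearest-centroid linking of measured objects across frames. Spores
#' are essentially motionless under the agar pad, so candidate matches are
#' restricted to displacements below \code{maxDispUm}; candidates are
#' assigned in order of increasing distance, ties broken by smallest
#' relative area change and then lowest label, which makes the assignment
#' deterministic. Unmatched objects start new tracks. A track tolerates up
#' to \code{maxGap} consecutive missing frames (frames listed in
#' \code{excludeFrames}, e.g. focus-loss frames, are dropped before linking
#' and do not count against the gap allowance); gap rows are filled by
#' linear interpolation and flagged \code{interpolated}. When a track ends
#' and at least two tracks begin at the next kept frame with centroids near
#' the parent and combined area within 30 percent of the parent's, the
#' parent's terminal event is recorded as a split (the daughters of a
#' division); otherwise a track ending before the last frame is
#' \code{"lost"}.
#'
#' @param meas measurement data.frame from \code{\link{measureAll}} (sorted
#'   by frame then label).
#' @param maxDispUm maximum centroid displacement per frame step (default 2).
#' @param maxAreaChange maximum relative area change for a link (default
#'   0.45): an object that halves its area between frames — a division —
#'   must not be linked as the same particle, which is what lets the split
#'   event be recorded.
#' @param maxGap maximum unexcused missing frames inside a track (default 2).
#' @param excludeFrames 0-based frame indices to drop before linking
#'   (focus-loss frames).
#' @param nFramesTotal total frames in the source stack; defaults to
#'   \code{max(meas$frame) + 1}.
#' @param pixelSizeUm,frameIntervalMin calibration stored in the result.
#' @return A \linkS4class{TrackSet}.
#' @export
linkTracks <- function(meas, maxDispUm = 2.0, maxAreaChange = 0.45,
                       maxGap = 2L,
                       excludeFrames = integer(0), nFramesTotal = NULL,
                       pixelSizeUm = 0.18, frameIntervalMin = 10) {
  stopifnot(is.data.frame(meas))
  if (is.null(nFramesTotal))
    nFramesTotal <- if (nrow(meas)) max(meas$frame) + 1L else 0L
  nFramesTotal <- as.integer(nFramesTotal)
  if (!"degenerate" %in% names(meas)) meas$degenerate <- FALSE
  keep <- !(meas$frame %in% excludeFrames)
  meas <- meas[keep, , drop = FALSE]
  rownames(meas) <- NULL
  keptFrames <- setdiff(seq_len(nFramesTotal) - 1L, excludeFrames)
  lastKept <- if (length(keptFrames)) max(keptFrames) else -1L
  isEx <- rep(FALSE, max(nFramesTotal, 1L))
  isEx[excludeFrames + 1L] <- TRUE

  rowsByFrame <- split(seq_len(nrow(meas)), meas$frame)

  maxTracks <- nrow(meas) + 1L
  trackRows <- vector("list", maxTracks)  # meas row indices per track
  startF <- endF <- integer(maxTracks)
  # open-track state vectors
  oId <- integer(0); oF <- integer(0)
  oX <- oY <- oA <- numeric(0)
  nextId <- 1L

  for (f in keptFrames) {
    rix <- rowsByFrame[[as.character(f)]]
    nObj <- length(rix)
    # retire tracks whose unexcused gap allowance is exhausted
    if (length(oId)) {
      gapTot <- f - oF - 1L
      exIn <- vapply(seq_along(oId), function(k) {
        if (gapTot[k] <= 0L) 0L else sum(isEx[(oF[k] + 2L):f])
      }, integer(1))
      alive <- (gapTot - exIn) <= maxGap | oF == f - 1L
      alive[oF >= f] <- TRUE
      oId <- oId[alive]; oF <- oF[alive]
      oX <- oX[alive]; oY <- oY[alive]; oA <- oA[alive]
    }
    assigned <- rep(FALSE, nObj)
    if (length(oId) && nObj) {
      ox <- meas$centroid_x_um[rix]; oy <- meas$centroid_y_um[rix]
      oa <- meas$area_um2[rix]; olab <- meas$label[rix]
      D <- sqrt(outer(oX, ox, "-")^2 + outer(oY, oy, "-")^2)
      dRel <- abs(outer(oA, oa, "-")) / oA
      cand <- which(D <= maxDispUm & dRel <= maxAreaChange, arr.ind = TRUE)
      if (nrow(cand)) {
        dist <- D[cand]
        dA <- dRel[cand]
        lb <- olab[cand[, 2L]]
        ord <- order(dist, dA, lb)
        usedT <- rep(FALSE, length(oId))
        for (k in ord) {
          ti <- cand[k, 1L]; j <- cand[k, 2L]
          if (usedT[ti] || assigned[j]) next
          usedT[ti] <- TRUE; assigned[j] <- TRUE
          id <- oId[ti]
          trackRows[[id]] <- c(trackRows[[id]], rix[j])
          oF[ti] <- f; oX[ti] <- ox[j]; oY[ti] <- oy[j]; oA[ti] <- oa[j]
          endF[id] <- f
        }
      }
    }
    if (nObj && any(!assigned)) {
      for (j in which(!assigned)) {
        id <- nextId; nextId <- nextId + 1L
        trackRows[[id]] <- rix[j]
        startF[id] <- f; endF[id] <- f
        oId <- c(oId, id); oF <- c(oF, f)
        oX <- c(oX, meas$centroid_x_um[rix[j]])
        oY <- c(oY, meas$centroid_y_um[rix[j]])
        oA <- c(oA, meas$area_um2[rix[j]])
      }
    }
  }

  nTr <- nextId - 1L
  events <- data.frame(track_id = seq_len(nTr),
                       start_frame = startF[seq_len(nTr)],
                       end_frame = endF[seq_len(nTr)],
                       terminal_event = rep("none", nTr),
                       split_frame = NA_integer_,
                       child1 = NA_integer_, child2 = NA_integer_,
                       stringsAsFactors = FALSE)
  if (nTr) events$terminal_event[events$end_frame < lastKept] <- "lost"

  # split detection
  if (nTr && any(events$terminal_event == "lost")) {
    nextKeptOf <- function(f) {
      k <- keptFrames[keptFrames > f]
      if (length(k)) k[1L] else NA_integer_
    }
    firstRow <- vapply(seq_len(nTr), function(id) trackRows[[id]][1L],
                       integer(1))
    lastRowI <- vapply(seq_len(nTr), function(id)
      trackRows[[id]][length(trackRows[[id]])], integer(1))
    for (id in which(events$terminal_event == "lost")) {
      li <- lastRowI[id]
      fN <- nextKeptOf(meas$frame[li])
      if (is.na(fN)) next
      starters <- which(events$start_frame == fN & events$track_id != id)
      if (length(starters) < 2L) next
      sx <- meas$centroid_x_um[firstRow[starters]]
      sy <- meas$centroid_y_um[firstRow[starters]]
      sa <- meas$area_um2[firstRow[starters]]
      dd <- sqrt((sx - meas$centroid_x_um[li])^2 +
                   (sy - meas$centroid_y_um[li])^2)
      # daughters of a long cell sit half its length from the parent
      # centroid, so the search radius scales with the parent's major axis
      srch <- meas$major_um[li] / 2 + maxDispUm
      ord <- order(dd)
      ord <- ord[dd[ord] <= srch]
      if (length(ord) < 2L) next
      pick <- ord[1:2]
      if (abs(sum(sa[pick]) - meas$area_um2[li]) / meas$area_um2[li] <= 0.30) {
        events$terminal_event[id] <- "split"
        events$split_frame[id] <- fN
        events$child1[id] <- events$track_id[starters[pick[1L]]]
        events$child2[id] <- events$track_id[starters[pick[2L]]]
      }
    }
  }

  # assemble long table with interpolated gap rows
  pieces <- vector("list", nTr)
  for (id in seq_len(nTr)) {
    tr <- meas[trackRows[[id]], , drop = FALSE]
    tr$track_id <- id
    tr$interpolated <- FALSE
    fr <- tr$frame
    want <- seq.int(fr[1L], fr[length(fr)])
    miss <- setdiff(want, fr)
    if (length(miss)) {
      fill <- data.frame(frame = miss)
      for (cc in c("centroid_x_um", "centroid_y_um", "area_um2", "major_um",
                   "minor_um", "orientation_rad"))
        fill[[cc]] <- approx(fr, tr[[cc]], xout = miss)$y
      fill$aspect_ratio <- fill$major_um / fill$minor_um
      fill$label <- NA_integer_
      fill$degenerate <- FALSE
      fill$track_id <- id
      fill$interpolated <- TRUE
      tr <- rbind(tr, fill[, names(tr)])
      tr <- tr[order(tr$frame), , drop = FALSE]
    }
    pieces[[id]] <- tr
  }
  m <- if (nTr) do.call(rbind, pieces) else
    data.frame(track_id = integer(), frame = integer(), label = integer(),
               centroid_x_um = numeric(), centroid_y_um = numeric(),
               area_um2 = numeric(), major_um = numeric(),
               minor_um = numeric(), aspect_ratio = numeric(),
               orientation_rad = numeric(), degenerate = logical(),
               interpolated = logical())
  first <- c("track_id", "frame", "label", "centroid_x_um", "centroid_y_um",
             "area_um2", "major_um", "minor_um", "aspect_ratio",
             "orientation_rad", "interpolated", "degenerate")
  m <- m[, first, drop = FALSE]
  rownames(m) <- NULL
  new("TrackSet", measurements = m, events = events,
      pixelSizeUm = pixelSizeUm, frameIntervalMin = frameIntervalMin,
      nFrames = nFramesTotal)
}

#' Write a track table to CSV
#'
#' Long-format CSV (one row per track and frame) with the per-track terminal
#' event joined on; round-trips through \code{\link{readTracks}}.
#'
#' @param trackset a \linkS4class{TrackSet}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTracks <- function(trackset, path) {
  stopifnot(is(trackset, "TrackSet"))
  m <- trackset@measurements
  ev <- trackset@events[, c("track_id", "terminal_event", "split_frame",
                            "child1", "child2")]
  out <- merge(m, ev, by = "track_id", sort = FALSE)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 9))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track table written by \code{\link{writeTracks}}
#'
#' @param path CSV path.
#' @param pixelSizeUm,frameIntervalMin calibration for the rebuilt object.
#' @return A \linkS4class{TrackSet}.
#' @export
readTracks <- function(path, pixelSizeUm = 0.18, frameIntervalMin = 10) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  mcols <- c("track_id", "frame", "label", "centroid_x_um", "centroid_y_um",
             "area_um2", "major_um", "minor_um", "aspect_ratio",
             "orientation_rad", "interpolated", "degenerate")
  m <- tab[, mcols]
  ev <- unique(tab[, c("track_id", "terminal_event", "split_frame",
                       "child1", "child2")])
  agg <- aggregate(frame ~ track_id, data = m, FUN = range)
  events <- data.frame(track_id = agg$track_id,
                       start_frame = agg$frame[, 1L],
                       end_frame = agg$frame[, 2L])
  events <- merge(events, ev, by = "track_id")
  events <- events[order(events$track_id), ]
  rownames(events) <- NULL
  new("TrackSet", measurements = m, events = events,
      pixelSizeUm = pixelSizeUm, frameIntervalMin = frameIntervalMin,
      nFrames = max(m$frame) + 1L)
}
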