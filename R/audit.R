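#' Write per-track montages for manual audit
#'
#' Emits one grayscale PNG montage per sampled track: the cell's cropped
#' neighbourhood at evenly spaced frames, annotated only by file name
#' (track id and called phenotype). Mirrors the practice of manually
#' confirming algorithm outputs on a random sample of at least 30 cells
#' per sample; the audit is a report for a human reviewer, not a pipeline
#' gate.
#'
#' @param stack an \linkS4class{ImageStack} (or \code{NULL} to render from
#'   the label masks instead).
#' @param labels the \linkS4class{LabelStack} used for the calls.
#' @param trackset a \linkS4class{TrackSet}.
#' @param calls data.frame from \code{\link{phenotypeTracks}}.
#' @param outDir output directory (created if needed).
#' @param n number of gated tracks to sample (default 30; all if fewer).
#' @param nFramesShown montage columns (default 8).
#' @param marginUm crop margin around the track's bounding box (default 2).
#' @param seed sampling seed.
#' @return Invisibly, the written file paths.
#' @export
writeAuditMontages <- function(stack, labels, trackset, calls, outDir,
                               n = 30L, nFramesShown = 8L, marginUm = 2,
                               seed = 1L) {
  stopifnot(is(labels, "LabelStack"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  gated <- calls$track_id[calls$is_spore]
  picks <- .withSeed(seed, {
    if (length(gated) <= n) sort(gated) else sort(sample(gated, n))
  })
  m <- measurements(trackset)
  pxsz <- pixelSize(labels)
  H <- dim(labels@labels)[1L]; W <- dim(labels@labels)[2L]
  files <- character(0)
  for (id in picks) {
    tr <- m[m$track_id == id & !m$interpolated, , drop = FALSE]
    mar <- marginUm / pxsz
    j0 <- max(1L, floor(min(tr$centroid_x_um - tr$major_um / 2) / pxsz - mar))
    j1 <- min(W, ceiling(max(tr$centroid_x_um + tr$major_um / 2) / pxsz + mar))
    i0 <- max(1L, floor(min(tr$centroid_y_um - tr$major_um / 2) / pxsz - mar))
    i1 <- min(H, ceiling(max(tr$centroid_y_um + tr$major_um / 2) / pxsz + mar))
    fr <- unique(round(seq(min(tr$frame), max(tr$frame),
                           length.out = min(nFramesShown, nrow(tr)))))
    tiles <- lapply(fr, function(f) {
      if (!is.null(stack)) {
        getFrame(stack, f + 1L)[i0:i1, j0:j1]
      } else {
        (labels@labels[i0:i1, j0:j1, f + 1L] > 0L) * 0.8 + 0.1
      }
    })
    sep <- matrix(1, i1 - i0 + 1L, 2L)
    strip <- do.call(cbind, Reduce(function(a, b) c(a, list(sep), list(b)),
                                   tiles[-1L], list(tiles[[1L]])))
    strip <- pmin(pmax(strip, 0), 1)
    ph <- calls$phenotype[match(id, calls$track_id)]
    fn <- file.path(outDir, sprintf("track%04d_%s.png", id,
                                    if (is.na(ph)) "unscored" else ph))
    png::writePNG(strip, fn)
    files <- c(files, fn)
  }
  invisible(files)
}
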