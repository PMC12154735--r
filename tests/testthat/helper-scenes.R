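# shared fixtures: tiny scenes are generated once per session and cached

.sceneCache <- new.env(parent = emptyenv())

cachedScene <- function(key, scenario, render = "labels") {
  full <- paste(key, render)
  if (is.null(.sceneCache[[full]]))
    .sceneCache[[full]] <- simulateScene(scenario, render = render)
  .sceneCache[[full]]
}

# match ground-truth cells to track ids by time-zero centroid
matchTruthTracks <- function(trackset, truth) {
  m <- measurements(trackset)
  m0 <- m[m$frame == 0 & !m$interpolated, ]
  cells <- truth$cells
  vapply(seq_len(nrow(cells)), function(i) {
    d <- sqrt((m0$centroid_x_um - cells$x_um[i])^2 +
                (m0$centroid_y_um - cells$y_um[i])^2)
    m0$track_id[which.min(d)]
  }, numeric(1))
}

runPipeline <- function(sim, config = pipelineConfig(), withLabels = TRUE) {
  meas <- measureAll(sim$labels)
  ts <- linkTracks(meas, nFramesTotal = nFrames(sim$labels),
                   pixelSizeUm = pixelSize(sim$labels),
                   frameIntervalMin = frameInterval(sim$labels))
  calls <- phenotypeTracks(ts, if (withLabels) sim$labels else NULL, config)
  list(trackset = ts, calls = calls)
}

# rasterize a filled disc the dumb way (independent oracle for masks)
rasterDiscPixels <- function(cx, cy, r, H, W) {
  out <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if ((j - 0.5 - cx)^2 + (i - 0.5 - cy)^2 <= r^2)
      out <- rbind(out, c(i, j))
  }
  out
}
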