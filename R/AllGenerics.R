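#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, t, channel = 1L) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname accessors
#' @export
setGeneric("trackEvents", function(x) standardGeneric("trackEvents"))

#' Accessors for germquant containers
#'
#' \code{frames} returns the intensity array of an \linkS4class{ImageStack};
#' \code{labelData} the label array of a \linkS4class{LabelStack} (named to
#' avoid masking \code{base::labels}); \code{pixelSize} and
#' \code{frameInterval} the physical calibration; \code{nFrames} the number of
#' timepoints; \code{channelNames} the channel names; \code{getFrame} one 2-D
#' frame; \code{measurements} and \code{trackEvents} the long measurement
#' table and per-track event table of a \linkS4class{TrackSet}.
#'
#' @param x a germquant container.
#' @param t frame index (1-based).
#' @param channel channel index (1-based), for multi-channel stacks.
#' @return See details; scalar calibration values, arrays, matrices or
#'   data.frames as appropriate.
#' @name accessors
NULL

#' @rdname accessors
setMethod("frames", "ImageStack", function(x) x@frames)
#' @rdname accessors
setMethod("labelData", "LabelStack", function(x) x@labels)
#' @rdname accessors
setMethod("pixelSize", "ImageStack", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "LabelStack", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "TrackSet", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("frameInterval", "ImageStack", function(x) x@frameIntervalMin)
#' @rdname accessors
setMethod("frameInterval", "LabelStack", function(x) x@frameIntervalMin)
#' @rdname accessors
setMethod("frameInterval", "TrackSet", function(x) x@frameIntervalMin)
#' @rdname accessors
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3L])
#' @rdname accessors
setMethod("nFrames", "LabelStack", function(x) dim(x@labels)[3L])
#' @rdname accessors
setMethod("nFrames", "TrackSet", function(x) x@nFrames)
#' @rdname accessors
setMethod("channelNames", "ImageStack", function(x) x@channelNames)
#' @rdname accessors
setMethod("getFrame", "ImageStack", function(x, t, channel = 1L) {
  d <- dim(x@frames)
  if (t < 1L || t > d[3L]) stop("frame index out of range")
  if (length(d) == 4L) x@frames[, , t, channel] else x@frames[, , t]
})
#' @rdname accessors
setMethod("getFrame", "LabelStack", function(x, t, channel = 1L) {
  if (t < 1L || t > dim(x@labels)[3L]) stop("frame index out of range")
  x@labels[, , t]
})
#' @rdname accessors
setMethod("measurements", "TrackSet", function(x) x@measurements)
#' @rdname accessors
setMethod("trackEvents", "TrackSet", function(x) x@events)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  nc <- if (length(d) == 4L) d[4L] else 1L
  cat(sprintf("ImageStack: %d frame(s), %d x %d px, %d channel(s)\n",
              d[3L], d[1L], d[2L], nc))
  cat(sprintf("  calibration: %.4g um/px, %.4g min/frame\n",
              object@pixelSizeUm, object@frameIntervalMin))
  cat(sprintf("  channels: %s\n", paste(object@channelNames, collapse = ", ")))
})

setMethod("show", "LabelStack", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelStack: %d frame(s), %d x %d px, max label %d\n",
              d[3L], d[1L], d[2L], max(object@labels)))
  cat(sprintf("  calibration: %.4g um/px, %.4g min/frame\n",
              object@pixelSizeUm, object@frameIntervalMin))
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d track(s), %d measurement row(s), %d frame(s)\n",
              nrow(object@events), nrow(object@measurements), object@nFrames))
  ev <- table(object@events$terminal_event)
  cat("  terminal events:",
      paste(sprintf("%s=%d", names(ev), as.integer(ev)), collapse = " "), "\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  pixel size    : %.4g um/px\n", object@pixelSizeUm))
  cat(sprintf("  frame interval: %.4g min\n", object@frameIntervalMin))
  cat(sprintf("  spore gate    : AR < %.3g at t0\n", object@sporeARMax))
  cat(sprintf("  division      : AR > %.3g\n", object@divisionAR))
  cat(sprintf("  elongated     : outgrowth > %.3g um\n",
              object@elongatedCutoffUm))
  cat(sprintf("  focus loss    : exclude if > %d frames\n",
              object@focusLossMaxFrames))
})

setMethod("show", "ScenarioConfig", function(object) {
  p <- object@params
  cat(sprintf("ScenarioConfig: %d spore(s), %d debris, %.0f min @ %.0f min/frame\n",
              p$n_spores, p$n_debris, p$duration_min, p$frame_interval_min))
  cat("  phenotype mix:",
      paste(sprintf("%s=%.2f", names(p$phenotype_mix), p$phenotype_mix),
            collapse = " "), "\n")
  cat(sprintf("  seed: %d\n", p$seed))
})

setMethod("show", "DecayModel", function(object) {
  cat(sprintf("DecayModel (%s): half-life %s d, noise sd(log) %.3g\n",
              object@form,
              paste(signif(object@halfLifeDays, 4), collapse = "/"),
              object@noiseSdLog))
})
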