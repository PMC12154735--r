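#' @import methods
#' @importFrom stats median mad rnorm rlnorm rgamma runif sd var pf pt qt
#'   dhyper approx setNames aggregate uniroot quantile rbinom qbeta
#' @importFrom utils read.csv write.csv head tail
NULL

#' Pipeline configuration
#'
#' Holds the calibration values and scoring thresholds used throughout the
#' germination pipeline. All length thresholds are in micrometres, times in
#' minutes, and aspect ratios are unitless (major/minor axis of the
#' moment-matching ellipse). Defaults reproduce the published scoring rules:
#' objects are gated as spores when their aspect ratio at time point zero is
#' below \code{sporeARMax} (1.4), the first division is called when the aspect
#' ratio exceeds \code{divisionAR} (3.0), outgrowths longer than
#' \code{elongatedCutoffUm} (6) are scored elongated, and a timelapse is
#' excluded when more than \code{focusLossMaxFrames} (5) frames lost focus.
#'
#' @slot pixelSizeUm physical pixel size (um/pixel), default 0.18.
#' @slot frameIntervalMin minutes between frames, default 10.
#' @slot durationMinDefault default timelapse length in minutes, default 1000.
#' @slot sporeARMax aspect-ratio gate at frame 0 (strict \code{<}), default 1.4.
#' @slot divisionAR aspect ratio defining the first division (strict
#'   \code{>}), default 3.0.
#' @slot elongatedCutoffUm outgrowth length above which a cell is scored
#'   elongated, default 6.
#' @slot focusLossMaxFrames more than this many focus-loss frames excludes the
#'   timelapse, default 5.
#' @slot smoothingWindowFrames odd moving-average window used by swelling
#'   detection, default 3.
#' @slot swellingAreaEps relative area slope per frame that counts as growth,
#'   default 0.01.
#' @slot swellingAREps absolute AR slope per frame still considered "no AR
#'   increase", default 0.02.
#' @slot bubbleARMax a split below this aspect ratio is a bubble division,
#'   default 1.6.
#' @slot explodeAreaDropFrac fractional area loss within two frames that marks
#'   an explosion, default 0.5.
#' @slot bipolarMinProtrusionUm minimum per-pole protrusion for a bipolar call
#'   (tube radius + 0.5 um), default 1.5.
#' @slot rngSeed integer seed recorded with the run.
#' @export
setClass("PipelineConfig", representation(
  pixelSizeUm = "numeric",
  frameIntervalMin = "numeric",
  durationMinDefault = "numeric",
  sporeARMax = "numeric",
  divisionAR = "numeric",
  elongatedCutoffUm = "numeric",
  focusLossMaxFrames = "integer",
  smoothingWindowFrames = "integer",
  swellingAreaEps = "numeric",
  swellingAREps = "numeric",
  bubbleARMax = "numeric",
  explodeAreaDropFrac = "numeric",
  bipolarMinProtrusionUm = "numeric",
  rngSeed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  pos <- c(
    pixelSizeUm = object@pixelSizeUm,
    frameIntervalMin = object@frameIntervalMin,
    durationMinDefault = object@durationMinDefault,
    sporeARMax = object@sporeARMax,
    divisionAR = object@divisionAR,
    elongatedCutoffUm = object@elongatedCutoffUm,
    swellingAreaEps = object@swellingAreaEps,
    swellingAREps = object@swellingAREps,
    bubbleARMax = object@bubbleARMax,
    explodeAreaDropFrac = object@explodeAreaDropFrac,
    bipolarMinProtrusionUm = object@bipolarMinProtrusionUm
  )
  for (nm in names(pos)) {
    if (!num1(pos[[nm]]) || pos[[nm]] <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", nm))
  }
  if (num1(object@sporeARMax) && num1(object@divisionAR) &&
      object@sporeARMax >= object@divisionAR)
    msg <- c(msg, "'sporeARMax' must be smaller than 'divisionAR'")
  if (length(object@focusLossMaxFrames) != 1L || object@focusLossMaxFrames < 0L)
    msg <- c(msg, "'focusLossMaxFrames' must be a single non-negative integer")
  w <- object@smoothingWindowFrames
  if (length(w) != 1L || w < 1L || w %% 2L == 0L)
    msg <- c(msg, "'smoothingWindowFrames' must be an odd integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Calibrated multi-frame image stack
#'
#' A timelapse of one field of view: intensities with physical calibration.
#' Frames are stored as an array with dimensions height x width x frames
#' (x channels when more than one channel is present). Pixel centres sit at
#' \code{(index - 0.5) * pixelSizeUm} and the time of frame \code{k} (1-based)
#' is \code{(k - 1) * frameIntervalMin} minutes, so frame 1 is time point zero.
#'
#' @slot frames numeric array, H x W x T or H x W x T x C, non-negative.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot frameIntervalMin minutes between consecutive frames.
#' @slot channelNames character vector, one name per channel.
#' @export
setClass("ImageStack", representation(
  frames = "array",
  pixelSizeUm = "numeric",
  frameIntervalMin = "numeric",
  channelNames = "character"
))

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  msg <- character()
  if (!(length(d) %in% c(3L, 4L)))
    msg <- c(msg, "'frames' must be an H x W x T (x C) array")
  else {
    if (any(d[1:3] < 1L)) msg <- c(msg, "all of H, W, T must be >= 1")
    nc <- if (length(d) == 4L) d[4L] else 1L
    if (length(object@channelNames) != nc)
      msg <- c(msg, "'channelNames' must have one entry per channel")
  }
  rng <- suppressWarnings(range(object@frames))   # no elementwise temps
  if (anyNA(rng) || !all(is.finite(rng)) || rng[1L] < 0)
    msg <- c(msg, "intensities must be finite and non-negative")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (length(object@frameIntervalMin) != 1L || object@frameIntervalMin <= 0)
    msg <- c(msg, "'frameIntervalMin' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Per-frame label masks
#'
#' Integer label images for a timelapse: 0 is background and each positive
#' label is one connected component within its frame. This is the common
#' container for masks produced by \code{\link{segmentStack}} and for
#' externally produced masks (e.g. from a learned segmenter) imported with
#' \code{\link{loadExternalMasks}}; downstream behaviour is identical for
#' either source.
#'
#' @slot labels integer array, H x W x T.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot frameIntervalMin minutes between consecutive frames.
#' @export
setClass("LabelStack", representation(
  labels = "array",
  pixelSizeUm = "numeric",
  frameIntervalMin = "numeric"
))

setValidity("LabelStack", function(object) {
  d <- dim(object@labels)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "'labels' must be an H x W x T array")
  if (!is.integer(object@labels))
    msg <- c(msg, "'labels' must be integer-valued (storage mode integer)")
  else if (length(object@labels) && min(object@labels) < 0L)
    msg <- c(msg, "labels must be non-negative")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (length(object@frameIntervalMin) != 1L || object@frameIntervalMin <= 0)
    msg <- c(msg, "'frameIntervalMin' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Linked particle tracks
#'
#' The result of \code{\link{linkTracks}}: per-frame ellipse measurements of
#' every tracked object plus the terminal event of each track. Measurements
#' are long-format, one row per (track, frame); the \code{interpolated} column
#' flags rows filled across short gaps rather than measured.
#'
#' @slot measurements data.frame with columns \code{track_id, frame, label,
#'   centroid_x_um, centroid_y_um, area_um2, major_um, minor_um,
#'   aspect_ratio, orientation_rad, interpolated, degenerate}.
#' @slot events data.frame with one row per track: \code{track_id,
#'   start_frame, end_frame, terminal_event} (\code{"none"}, \code{"split"} or
#'   \code{"lost"}), \code{split_frame}, \code{child1}, \code{child2}.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot frameIntervalMin minutes between consecutive frames.
#' @slot nFrames total number of frames in the source stack.
#' @export
setClass("TrackSet", representation(
  measurements = "data.frame",
  events = "data.frame",
  pixelSizeUm = "numeric",
  frameIntervalMin = "numeric",
  nFrames = "integer"
))

setValidity("TrackSet", function(object) {
  need <- c("track_id", "frame", "label", "centroid_x_um", "centroid_y_um",
            "area_um2", "major_um", "minor_um", "aspect_ratio",
            "orientation_rad", "interpolated")
  msg <- character()
  if (!all(need %in% names(object@measurements)))
    msg <- c(msg, paste("measurements must contain columns:",
                        paste(setdiff(need, names(object@measurements)),
                              collapse = ", ")))
  ev <- c("track_id", "start_frame", "end_frame", "terminal_event")
  if (!all(ev %in% names(object@events)))
    msg <- c(msg, "events must contain track_id/start_frame/end_frame/terminal_event")
  if (length(msg)) msg else TRUE
})

#' Synthetic scene scenario
#'
#' Parameters of the synthetic timelapse generator. The generator emulates
#' germinating fission-yeast spores trapped under agar: circular dormant
#' spores with true areas around 7-9 um^2, a dormancy lag, an isotropic
#' swelling phase (area up, aspect ratio flat), polarized tube outgrowth and
#' a first division called when the analytic moment-ellipse aspect ratio of
#' the cell reaches \code{divisionAR}, plus the aberrant phenotype classes
#' (elongated, bubble, bipolar, exploded), dead spores, and debris.
#'
#' @slot params named list of generator parameters; see
#'   \code{\link{scenarioConfig}} for the full set and defaults.
#' @export
setClass("ScenarioConfig", representation(params = "list"))

setValidity("ScenarioConfig", function(object) {
  p <- object@params
  msg <- character()
  mix <- p$phenotype_mix
  if (abs(sum(mix) - 1) > 1e-8) msg <- c(msg, "phenotype_mix must sum to 1")
  if (any(mix < 0)) msg <- c(msg, "phenotype_mix must be non-negative")
  if (!setequal(names(mix), c("normal", "elongated", "bubble", "bipolar",
                              "exploded", "dead")))
    msg <- c(msg, "phenotype_mix must name the six classes")
  for (nm in c("spore_radius_um", "lag_mean_min", "swell_duration_min",
               "tube_width_um", "tube_speed_um_per_frame", "duration_min",
               "frame_interval_min", "pixel_size_um"))
    if (!is.numeric(p[[nm]]) || any(p[[nm]] <= 0))
      msg <- c(msg, sprintf("'%s' must be positive", nm))
  r <- p$elongated_outgrowth_range_um
  if (length(r) != 2L || r[1] >= r[2])
    msg <- c(msg, "elongated_outgrowth_range_um must be an increasing pair")
  if (r[1] <= p$elongated_cutoff_um)
    msg <- c(msg, "elongated outgrowth range must start above elongated_cutoff_um")
  if (p$n_spores < 0 || p$n_debris < 0)
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Spore viability decay model
#'
#' Parametric survival-fraction model for colony-forming-unit (CFU) longevity
#' experiments: exponential (one half-life) or biphasic (mixture of two
#' exponentials). Used by \code{\link{simulateCFUExperiment}} to generate
#' replicate CFU series with multiplicative log-normal count noise.
#'
#' @slot form \code{"exponential"} or \code{"biphasic"}.
#' @slot halfLifeDays half-life in days (exponential), or the two half-lives
#'   (biphasic).
#' @slot mixWeight weight of the first component for biphasic models.
#' @slot noiseSdLog standard deviation of log-normal replicate noise.
#' @export
setClass("DecayModel", representation(
  form = "character",
  halfLifeDays = "numeric",
  mixWeight = "numeric",
  noiseSdLog = "numeric"
))

setValidity("DecayModel", function(object) {
  msg <- character()
  if (!object@form %in% c("exponential", "biphasic"))
    msg <- c(msg, "form must be 'exponential' or 'biphasic'")
  if (any(object@halfLifeDays <= 0)) msg <- c(msg, "half-lives must be > 0")
  if (object@form == "biphasic" && length(object@halfLifeDays) != 2L)
    msg <- c(msg, "biphasic models need two half-lives")
  if (object@form == "exponential" && length(object@halfLifeDays) != 1L)
    msg <- c(msg, "exponential models need one half-life")
  if (object@mixWeight < 0 || object@mixWeight > 1)
    msg <- c(msg, "mixWeight must be in [0, 1]")
  if (object@noiseSdLog < 0) msg <- c(msg, "noiseSdLog must be >= 0")
  if (length(msg)) msg else TRUE
})
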