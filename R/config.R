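.configDefaults <- list(
  pixel_size_um = 0.18,
  frame_interval_min = 10,
  duration_min_default = 1000,
  spore_ar_max = 1.4,
  division_ar = 3.0,
  elongated_cutoff_um = 6.0,
  focus_loss_max_frames = 5L,
  smoothing_window_frames = 3L,
  swelling_area_eps = 0.01,
  swelling_ar_eps = 0.02,
  bubble_ar_max = 1.6,
  explode_area_drop_frac = 0.5,
  bipolar_min_protrusion_um = 1.5,
  rng_seed = 1L
)

#' Create a pipeline configuration
#'
#' Builds a \linkS4class{PipelineConfig} from the published scoring defaults,
#' overriding any value passed by name. Keys use the snake_case names of the
#' on-disk config format (see \code{\link{loadConfig}}).
#'
#' @param ... named overrides, e.g. \code{pixel_size_um = 0.2},
#'   \code{division_ar = 3.0}.
#' @return A validated \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig()
#' cfg2 <- pipelineConfig(elongated_cutoff_um = 8)
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(.configDefaults))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  p <- utils::modifyList(.configDefaults, over)
  asInt <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
      stop(sprintf("configuration key '%s' must be a single integer", key))
    as.integer(x)
  }
  new("PipelineConfig",
      pixelSizeUm = as.numeric(p$pixel_size_um),
      frameIntervalMin = as.numeric(p$frame_interval_min),
      durationMinDefault = as.numeric(p$duration_min_default),
      sporeARMax = as.numeric(p$spore_ar_max),
      divisionAR = as.numeric(p$division_ar),
      elongatedCutoffUm = as.numeric(p$elongated_cutoff_um),
      focusLossMaxFrames = asInt(p$focus_loss_max_frames,
                                 "focus_loss_max_frames"),
      smoothingWindowFrames = asInt(p$smoothing_window_frames,
                                    "smoothing_window_frames"),
      swellingAreaEps = as.numeric(p$swelling_area_eps),
      swellingAREps = as.numeric(p$swelling_ar_eps),
      bubbleARMax = as.numeric(p$bubble_ar_max),
      explodeAreaDropFrac = as.numeric(p$explode_area_drop_frac),
      bipolarMinProtrusionUm = as.numeric(p$bipolar_min_protrusion_um),
      rngSeed = asInt(p$rng_seed, "rng_seed"))
}

#' Load a pipeline configuration file
#'
#' Reads a YAML key-value file; keys missing from the file take the package
#' defaults (the published thresholds), unknown keys or values violating the
#' configuration invariants raise an error naming the offending key. An empty
#' file yields the all-default configuration.
#'
#' @param path path to a YAML configuration file.
#' @return A validated \linkS4class{PipelineConfig}.
#' @seealso \code{\link{saveConfig}} for the inverse; the pair round-trips.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  vals <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed configuration file '", path, "': ", conditionMessage(e)))
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("configuration file must contain key: value pairs")
  for (k in names(vals)) {
    if (!k %in% names(.configDefaults))
      stop("unknown configuration key: ", k)
    if (!is.numeric(vals[[k]]) || length(vals[[k]]) != 1L)
      stop("configuration key '", k, "' must be a single number")
  }
  do.call(pipelineConfig, vals)
}

#' Write a pipeline configuration file
#'
#' Serializes a \linkS4class{PipelineConfig} to YAML such that
#' \code{loadConfig(saveConfig(cfg, path))} reproduces \code{cfg} exactly.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  vals <- list(
    pixel_size_um = config@pixelSizeUm,
    frame_interval_min = config@frameIntervalMin,
    duration_min_default = config@durationMinDefault,
    spore_ar_max = config@sporeARMax,
    division_ar = config@divisionAR,
    elongated_cutoff_um = config@elongatedCutoffUm,
    focus_loss_max_frames = config@focusLossMaxFrames,
    smoothing_window_frames = config@smoothingWindowFrames,
    swelling_area_eps = config@swellingAreaEps,
    swelling_ar_eps = config@swellingAREps,
    bubble_ar_max = config@bubbleARMax,
    explode_area_drop_frac = config@explodeAreaDropFrac,
    bipolar_min_protrusion_um = config@bipolarMinProtrusionUm,
    rng_seed = config@rngSeed
  )
  yaml::write_yaml(vals, path, precision = 15L)
  invisible(path)
}
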