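#' Detect focus-loss frames in a timelapse
#'
#' A frame where autofocus failed appears as a sharp dip or peak in measured
#' series; such frames are flagged from the images themselves. Per-frame
#' sharpness is the variance of the gradient magnitude of a lightly smoothed
#' copy of the frame (the smoothing suppresses sensor noise so the statistic
#' tracks true edge content). A frame is flagged when its sharpness falls
#' below \code{median - 3 * MAD} across frames, and the whole timelapse is
#' marked excluded when more than \code{focusLossMaxFrames} frames (strictly
#' more; default more than 5) are flagged. Flagged frames should be dropped
#' from per-track series; \code{\link{linkTracks}} interpolates across such
#' gaps and flags the filled rows.
#'
#' @param stack an \linkS4class{ImageStack} with at least 7 frames (enough
#'   for a robust baseline).
#' @param config a \linkS4class{PipelineConfig} supplying
#'   \code{focusLossMaxFrames}.
#' @param channel channel to analyse (default 1).
#' @return list with \code{flagged} (0-based frame indices), \code{excluded}
#'   (logical), and \code{sharpness} (per-frame statistic).
#' @export
detectFocusLoss <- function(stack, config = pipelineConfig(), channel = 1L) {
  stopifnot(is(stack, "ImageStack"))
  nT <- nFrames(stack)
  if (nT < 7L) stop("need at least 7 frames for a robust sharpness baseline")
  sharp <- numeric(nT)
  for (t in seq_len(nT)) {
    fr <- getFrame(stack, t, channel)
    sm <- as.matrix(EBImage::gblur(fr, sigma = 1))
    gx <- sm[, -1L, drop = FALSE] - sm[, -ncol(sm), drop = FALSE]
    gy <- sm[-1L, , drop = FALSE] - sm[-nrow(sm), , drop = FALSE]
    n <- min(length(gx), length(gy))
    g <- sqrt(gx[seq_len(n)]^2 + gy[seq_len(n)]^2)
    sharp[t] <- var(g)
  }
  med <- median(sharp)
  md <- mad(sharp)
  flagged <- which(sharp < med - 3 * md) - 1L   # report 0-based
  list(flagged = flagged,
       excluded = length(flagged) > config@focusLossMaxFrames,
       sharpness = sharp)
}
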