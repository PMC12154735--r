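#' Construct a viability decay model
#'
#' @param form \code{"exponential"} (one half-life) or \code{"biphasic"}
#'   (mixture of two exponentials).
#' @param halfLifeDays half-life in days; length 2 for biphasic models.
#' @param mixWeight weight of the first (typically faster) component for
#'   biphasic models.
#' @param noiseSdLog standard deviation of the multiplicative log-normal
#'   replicate noise applied to counts.
#' @return A \linkS4class{DecayModel}.
#' @export
decayModel <- function(form = c("exponential", "biphasic"),
                       halfLifeDays = 10, mixWeight = 0.5,
                       noiseSdLog = 0.05) {
  form <- match.arg(form)
  new("DecayModel", form = form, halfLifeDays = halfLifeDays,
      mixWeight = mixWeight, noiseSdLog = noiseSdLog)
}

#' Survival fraction of a decay model
#'
#' @param model a \linkS4class{DecayModel}.
#' @param days numeric vector of storage times (days).
#' @return Survival fractions in (0, 1].
#' @export
survivalFraction <- function(model, days) {
  stopifnot(is(model, "DecayModel"))
  if (model@form == "exponential") {
    2^(-days / model@halfLifeDays)
  } else {
    model@mixWeight * 2^(-days / model@halfLifeDays[1L]) +
      (1 - model@mixWeight) * 2^(-days / model@halfLifeDays[2L])
  }
}

#' Simulate a colony-forming-unit longevity experiment
#'
#' Replicate CFU counts over storage time: each count is the model's
#' survival fraction times the starting count times multiplicative
#' log-normal noise (mean-one parameterization). Deterministic given the
#' seed; replicates are drawn in replicate order, days within replicate.
#'
#' @param model a \linkS4class{DecayModel}.
#' @param days sampling days; must include day 0.
#' @param nReps number of replicates (>= 1).
#' @param startCfu expected day-0 count (default 400).
#' @param condition label stored in the output.
#' @param seed integer seed.
#' @return data.frame: \code{condition, replicate, day, cfu} (pass through
#'   \code{\link{normalizeCFU}} for the normalized fractions).
#' @export
simulateCFUExperiment <- function(model, days, nReps = 3L, startCfu = 400,
                                  condition = "condition", seed = 1L) {
  stopifnot(is(model, "DecayModel"))
  if (!0 %in% days) stop("sampling days must include day 0")
  if (nReps < 1L) stop("need at least one replicate")
  days <- sort(days)
  frac <- survivalFraction(model, days)
  .withSeed(seed, {
    out <- lapply(seq_len(nReps), function(r) {
      noise <- if (model@noiseSdLog > 0)
        rlnorm(length(days), meanlog = -model@noiseSdLog^2 / 2,
               sdlog = model@noiseSdLog)
      else rep(1, length(days))
      data.frame(condition = condition, replicate = r, day = days,
                 cfu = startCfu * frac * noise)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
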