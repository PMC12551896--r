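#' @include AllClasses.R
NULL

#' Per-neuron suppression index
#'
#' Contrast of each neuron's pre- vs post-training steady response,
#' `SI = (post - pre) / (post + pre)`, over a matched stimulus set.
#' With `perStimulus = TRUE` (default) the SI is computed for every
#' stimulus and then averaged across the set; with `FALSE` the rates
#' are first averaged across stimuli and a single ratio is taken.
#' Neurons whose stimulus-averaged rate is below `responsiveThreshold`
#' in both phases are excluded as non-responsive; a per-stimulus SI
#' with both rates zero is defined as 0.
#'
#' @param pre,post numeric matrices of steady rates, neurons x stimuli,
#'   with matched indexing.
#' @param responsiveThreshold minimum stimulus-averaged rate for a
#'   neuron to count as responsive in a phase (default 1e-3).
#' @param perStimulus average per-stimulus indices (default) or take
#'   the ratio of stimulus-averaged rates.
#' @return numeric vector of SI values (NA for excluded neurons), with
#'   attribute `retained` (logical vector).
#' @export
suppressionIndex <- function(pre, post, responsiveThreshold = 1e-3,
                             perStimulus = TRUE) {
  if (!all(dim(pre) == dim(post)))
    stop("pre and post matrices must have matching dimensions")
  avgPre <- rowMeans(pre)
  avgPost <- rowMeans(post)
  retained <- avgPre >= responsiveThreshold | avgPost >= responsiveThreshold
  si <- rep(NA_real_, nrow(pre))
  if (perStimulus) {
    num <- post - pre
    den <- post + pre
    ratio <- ifelse(den > 0, num / den, 0)
    si[retained] <- rowMeans(ratio)[retained]
  } else {
    den <- avgPost + avgPre
    si[retained] <- ifelse(den[retained] > 0,
                           (avgPost - avgPre)[retained] / den[retained], 0)
  }
  attr(si, "retained") <- retained
  si
}

#' Lifetime sparsity (Vinje-Gallant selectivity index)
#'
#' `S = n/(n-1) * (1 - (sum(r)/n)^2 / (sum(r^2)/n))` for a neuron's
#' tuning vector over `n` stimuli: 0 for a uniform tuning curve, 1 for
#' a one-hot curve.
#'
#' @param tuning nonnegative response vector over at least 2 stimuli.
#' @return sparsity in \[0,1\], or NA for an all-zero tuning curve.
#' @export
lifetimeSparsity <- function(tuning) {
  n <- length(tuning)
  if (n < 2) stop("need responses to at least 2 stimuli")
  if (any(tuning < 0)) stop("responses must be nonnegative")
  if (all(tuning == 0)) return(NA_real_)
  (n / (n - 1)) * (1 - (sum(tuning) / n)^2 / (sum(tuning^2) / n))
}

#' Relative pre/post change of a scalar metric
#'
#' `(post - pre) / (post + pre)`, in \[-1, 1\]; NA when both are zero.
#'
#' @param pre,post nonnegative scalars (vectorized).
#' @return relative change.
#' @export
relativeChange <- function(pre, post) {
  den <- pre + post
  ifelse(den > 0, (post - pre) / den, NA_real_)
}

#' Rank-ordered population tuning curve
#'
#' For every stimulus, sorts the neuron responses in descending order,
#' then averages across stimuli at each rank. Training-induced
#' sharpening shows as an increase at the top ranks and a decrease at
#' intermediate ranks.
#'
#' @param responses numeric matrix, neurons x stimuli.
#' @return numeric vector, mean response per rank.
#' @export
populationTuningCurve <- function(responses) {
  if (length(responses) == 0) stop("empty response matrix")
  sorted <- apply(responses, 2, sort, decreasing = TRUE)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, ncol = ncol(responses))
  rowMeans(sorted)
}

#' Population peri-stimulus time histogram
#'
#' Mean rate over neurons and stimuli per time step; with
#' `normalize = TRUE` the trace is divided by its peak so its maximum
#' is 1.
#'
#' @param traces list of equal-length population-mean rate traces (one
#'   per stimulus), or a matrix time x stimuli.
#' @param normalize divide by the peak response (default TRUE).
#' @return numeric vector, one value per time step.
#' @export
psth <- function(traces, normalize = TRUE) {
  if (is.list(traces)) {
    len <- unique(vapply(traces, length, integer(1)))
    if (length(len) != 1) stop("traces must have equal length")
    traces <- do.call(cbind, traces)
  }
  out <- rowMeans(traces)
  if (normalize && max(out) > 0) out <- out / max(out)
  out
}

#' Peak response of a tuning curve
#'
#' @param tuning response vector over stimuli.
#' @return the maximum response.
#' @export
peakResponse <- function(tuning) max(tuning)
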