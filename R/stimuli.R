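#' @include AllClasses.R utils.R
NULL

# periodic Gaussian low-pass of a white-noise field (FFT-based)
gaussianLowpass <- function(img, corrLength) {
  if (corrLength <= 0) return(img)
  n <- nrow(img)
  x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-x^2 / (2 * corrLength^2))
  K <- outer(k, k)
  K <- K / sum(K)
  Re(fft(fft(img) * fft(K), inverse = TRUE)) / n^2
}

#' Generate synthetic natural-image-like targets
#'
#' Spatially correlated random textures: Gaussian white noise low-pass
#' filtered at the requested correlation length, then min-max normalized
#' to \[0,1\] per image. These stand in for grayscale photographs as
#' familiarity-training targets; they reproduce the spatial correlation
#' and bounded range of natural images but none of their higher-order
#' structure.
#'
#' @param n number of targets.
#' @param side image side in pixels (default 32).
#' @param correlationLength Gaussian correlation length in pixels
#'   (default 3; 0 gives pixelwise-independent noise).
#' @param seed RNG seed; same seed gives identical targets.
#' @param minSide smallest side the downstream filter bank supports
#'   (default 9, one filter placement).
#' @return list of `side x side` matrices in \[0,1\].
#' @export
makeSyntheticTargets <- function(n, side = 32L, correlationLength = 3,
                                 seed = 1L, minSide = 9L) {
  if (n < 1) stop("n must be >= 1")
  if (side < minSide)
    stop("geometry error: side smaller than the filter support")
  withSeed(seed, lapply(seq_len(n), function(i) {
    img <- gaussianLowpass(matrix(rnorm(side^2), side, side),
                           correlationLength)
    rng <- range(img)
    if (diff(rng) < 1e-12) matrix(0.5, side, side)
    else (img - rng[1]) / diff(rng)
  }))
}

#' Occlude an image with salt-and-pepper noise
#'
#' Replaces `round(n * P)` distinct pixel positions (chosen uniformly
#' without replacement among the `P` pixels) with independent draws from
#' the uniform distribution on \[0,1\]; all other pixels are untouched.
#'
#' @param image grayscale matrix in \[0,1\].
#' @param n fraction of pixels to replace, in \[0,1\].
#' @param seed RNG seed for mask positions and replacement values.
#' @return occluded image matrix with attribute `replacedIdx` (the
#'   linear indices of the replacement mask).
#' @export
occlude <- function(image, n, seed = 1L) {
  if (n < 0 || n > 1) stop("noise fraction must be in [0, 1]")
  P <- length(image)
  m <- round(n * P)
  withSeed(seed, {
    idx <- sample.int(P, m)
    out <- image
    out[idx] <- runif(m)
    attr(out, "replacedIdx") <- sort(idx)
    out
  })
}

#' Build the clean-target familiarity stimulus set
#'
#' A set of `nImages` synthetic targets with no occlusion variants, the
#' stimulus ensemble of the familiarity-effects protocol (reference
#' scale: 25 images of 32 x 32 px).
#'
#' @inheritParams makeSyntheticTargets
#' @param nImages number of target images.
#' @return a [StimulusSet-class].
#' @export
buildFamiliaritySet <- function(nImages = 25L, side = 32L, seed = 1L,
                                correlationLength = 3) {
  targets <- makeSyntheticTargets(nImages, side, correlationLength, seed)
  stimuli <- lapply(seq_len(nImages), function(i)
    list(pixels = targets[[i]], id = sprintf("t%02d", i),
         targetId = sprintf("t%02d", i), level = 0,
         sample = 0L, seed = as.integer(seed)))
  new("StimulusSet", stimuli = stimuli, side = as.integer(side),
      levels = numeric(0), samplesPerLevel = 0L)
}

#' Build the association stimulus set (targets plus occluded variants)
#'
#' For each clean target, draws `samplesPerLevel` occlusion samples at
#' every noise level. With `T` targets, `L` levels and `K` samples per
#' level the set has `T * (1 + L*K)` stimuli; the reference protocol
#' (5 targets, levels 10/30/50%, 10 samples) gives 155. Each sample's
#' noise pattern is fixed by a seed hashed from `(baseSeed, target,
#' level, sample)`, so the variants form a fixed set across epochs.
#' Enumeration order is stable: per target, the clean image (level 0)
#' then variants by level then sample.
#'
#' @param targets list of grayscale matrices or a clean
#'   [StimulusSet-class] whose targets are used.
#' @param levels occlusion fractions (default `c(0.1, 0.3, 0.5)`).
#' @param samplesPerLevel noise samples per (target, level), default 10.
#' @param baseSeed base seed for the per-sample noise seeds.
#' @return a [StimulusSet-class].
#' @export
buildAssociationSet <- function(targets, levels = c(0.1, 0.3, 0.5),
                                samplesPerLevel = 10L, baseSeed = 1L) {
  if (is(targets, "StimulusSet"))
    targets <- lapply(targets@stimuli, function(s) s$pixels)
  if (length(targets) < 1) stop("targets must be nonempty")
  ids <- sprintf("t%02d", seq_along(targets))
  if (anyDuplicated(ids)) stop("duplicate target ids")
  stimuli <- list()
  for (l in seq_along(targets)) {
    stimuli[[length(stimuli) + 1L]] <-
      list(pixels = targets[[l]], id = ids[l], targetId = ids[l],
           level = 0, sample = 0L, seed = as.integer(baseSeed))
    for (lev in levels) for (k in seq_len(samplesPerLevel)) {
      sd <- hashSeed(baseSeed, ids[l], lev, k)
      px <- occlude(targets[[l]], lev, sd)
      attr(px, "replacedIdx") <- NULL
      stimuli[[length(stimuli) + 1L]] <-
        list(pixels = px, id = sprintf("%s_n%02d_k%02d", ids[l],
                                       round(100 * lev), k),
             targetId = ids[l], level = lev, sample = as.integer(k),
             seed = sd)
    }
  }
  new("StimulusSet", stimuli = stimuli,
      side = as.integer(nrow(targets[[1]])),
      levels = as.numeric(levels),
      samplesPerLevel = as.integer(samplesPerLevel))
}

#' Build per-epoch presentation schedules
#'
#' Each epoch presents every clean target `targetReps` times and every
#' occluded variant once, in a seeded random permutation; different
#' epochs use different permutations of the identical multiset.
#'
#' @param set a [StimulusSet-class].
#' @param targetReps presentations of each clean target per epoch
#'   (default 30).
#' @param seed base seed; epoch `e` shuffles with a seed hashed from
#'   `(seed, e)`.
#' @param nEpochs number of epochs to schedule.
#' @return list of integer vectors of stimulus indices, one per epoch.
#' @export
buildEpochSchedule <- function(set, targetReps = 30L, seed = 1L,
                               nEpochs = 1L) {
  info <- stimulusInfo(set)
  base <- c(rep(info$index[info$level == 0], targetReps),
            info$index[info$level > 0])
  lapply(seq_len(nEpochs), function(e)
    withSeed(hashSeed(seed, "epoch", e), sample(base)))
}
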