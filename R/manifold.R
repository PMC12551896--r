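#' @include AllClasses.R
NULL

#' Assemble fixed-point records into a table
#'
#' Collects steady-state excitatory responses for a stimulus set into a
#' `SummarizedExperiment`: one column per stimulus (assay `"rates"`,
#' neurons x stimuli) with the stimulus labels, convergence flags and
#' residuals in `colData`. This is the container all manifold metrics
#' operate on.
#'
#' @param records list of [FixedPointRecord-class] objects, one per
#'   stimulus, in stimulus-set enumeration order.
#' @param epoch optional probe epoch label stored in `metadata`.
#' @return a `SummarizedExperiment`.
#' @export
fixedPointTable <- function(records, epoch = NA_integer_) {
  rates <- vapply(records, function(x) x@rStar,
                  numeric(length(records[[1]]@rStar)))
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  cd <- S4Vectors::DataFrame(
    stimulusId = vapply(records, function(x) x@stimulusId, character(1)),
    targetId = vapply(records, function(x)
      sub("_n[0-9]+_k[0-9]+$", "", x@stimulusId), character(1)),
    level = vapply(records, function(x) x@noiseLevel, numeric(1)),
    sample = vapply(records, function(x) x@sampleIndex, integer(1)),
    converged = vapply(records, function(x) x@converged, logical(1)),
    residual = vapply(records, function(x) x@residual, numeric(1)))
  colnames(rates) <- cd$stimulusId
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rates = rates), colData = cd,
    metadata = list(epoch = epoch))
}

fptParts <- function(fpt, dropNonConverged = TRUE) {
  rates <- SummarizedExperiment::assay(fpt, "rates")
  cd <- as.data.frame(SummarizedExperiment::colData(fpt))
  if (dropNonConverged && any(!cd$converged)) {
    message(sum(!cd$converged), " non-converged stimuli excluded")
    keep <- cd$converged
    rates <- rates[, keep, drop = FALSE]
    cd <- cd[keep, , drop = FALSE]
  }
  list(rates = rates, info = cd)
}

pairwiseDist <- function(rates) as.matrix(stats::dist(t(rates)))

# adjacent-lower level lookup over the sorted unique levels present
lowerLevel <- function(levels) {
  u <- sort(unique(levels))
  function(n) {
    i <- match(n, u)
    if (is.na(i) || i == 1) NA_real_ else u[i - 1]
  }
}

#' Manifold distances of a fixed-point representation
#'
#' For every occluded sample (noise level `n > 0`, target `l`, sample
#' `k`) computes the mean Euclidean distances to: the samples of the
#' same target at the adjacent lower noise level (level distance, the
#' clean target being the single level-0 sample); the other samples of
#' the same target at the same level (residual distance); and all
#' samples of the other targets at the same level (signal distance).
#' Relative distances `Rlev = Dlev/Dsig` and `Rres = Dres/Dsig`
#' quantify compression of the variants manifold relative to the
#' concept manifold.
#'
#' @param fpt a fixed-point table from [fixedPointTable()].
#' @return data.frame with one row per (level, target, sample):
#'   `Dlev`, `Dres`, `Dsig`, `Rlev`, `Rres` (NA where undefined; a
#'   warning is given when `Dsig = 0`).
#' @export
distanceTable <- function(fpt) {
  p <- fptParts(fpt)
  info <- p$info
  D <- pairwiseDist(p$rates)
  low <- lowerLevel(info$level)
  rows <- which(info$level > 0)
  if (length(rows) == 0) stop("data error: no noisy levels in the table")
  out <- data.frame(targetId = info$targetId[rows],
                    level = info$level[rows],
                    sample = info$sample[rows],
                    Dlev = NA_real_, Dres = NA_real_, Dsig = NA_real_)
  for (ii in seq_along(rows)) {
    i <- rows[ii]
    n <- info$level[i]; l <- info$targetId[i]
    nl <- low(n)
    if (!is.na(nl)) {
      j <- which(info$targetId == l & info$level == nl)
      # partners can be absent when non-converged stimuli were dropped;
      # the distance is then undefined for this sample
      if (length(j) > 0) out$Dlev[ii] <- mean(D[i, j])
    }
    j <- which(info$targetId == l & info$level == n & seq_len(nrow(info)) != i)
    if (length(j) > 0) out$Dres[ii] <- mean(D[i, j])
    j <- which(info$targetId != l & info$level == n)
    if (length(j) > 0) out$Dsig[ii] <- mean(D[i, j])
  }
  if (any(!is.na(out$Dsig) & out$Dsig == 0))
    warning("zero signal distance; relative distances undefined there")
  out$Rlev <- ifelse(out$Dsig > 0, out$Dlev / out$Dsig, NA_real_)
  out$Rres <- ifelse(out$Dsig > 0, out$Dres / out$Dsig, NA_real_)
  out
}

#' Single level/residual/signal distances
#'
#' Scalar versions of the three distance classes of [distanceTable()]
#' for one (level, target, sample) triple.
#'
#' @param fpt a fixed-point table.
#' @param n noise level (must be > 0 and present in the table; for
#'   `levelDistance` the adjacent lower level must exist).
#' @param target target id (e.g. `"t01"`); not needed for
#'   `signalDistance`, where it names the reference sample's target.
#' @param sample sample index at that level.
#' @return the mean Euclidean distance (NA where undefined).
#' @export
levelDistance <- function(fpt, n, target, sample) {
  pickDistance(fpt, n, target, sample, "lev")
}

#' @rdname levelDistance
#' @export
residualDistance <- function(fpt, n, target, sample) {
  pickDistance(fpt, n, target, sample, "res")
}

#' @rdname levelDistance
#' @export
signalDistance <- function(fpt, n, target, sample) {
  pickDistance(fpt, n, target, sample, "sig")
}

pickDistance <- function(fpt, n, target, sample, what) {
  tab <- distanceTable(fpt)
  row <- tab[tab$level == n & tab$targetId == target &
               tab$sample == sample, ]
  if (nrow(row) != 1) stop("data error: no such (level, target, sample)")
  if (what == "lev" && is.na(row$Dlev))
    stop("data error: missing lower level for level ", n)
  switch(what, lev = row$Dlev, res = row$Dres, sig = row$Dsig)
}

#' Manifold-transform objective
#'
#' The compression objective of the learned representation: the sum
#' over stimuli of the mean squared distance to the same-target
#' variants divided by the mean squared distance to the stimuli of the
#' other targets. Decreases as the variants manifolds compress
#' relative to the concept manifold.
#'
#' @param fpt a fixed-point table.
#' @return the objective value.
#' @export
manifoldObjective <- function(fpt) {
  p <- fptParts(fpt)
  D2 <- pairwiseDist(p$rates)^2
  info <- p$info
  total <- 0
  for (i in seq_len(nrow(info))) {
    nb <- which(info$targetId == info$targetId[i] & seq_len(nrow(info)) != i)
    ot <- which(info$targetId != info$targetId[i])
    if (length(nb) == 0) stop("argument error: empty neighbor set")
    den <- mean(D2[i, ot])
    if (den > 0) total <- total + mean(D2[i, nb]) / den
  }
  total
}

#' Epoch-aggregated relative distances
#'
#' Means of `Rlev` and `Rres` over noise samples (per level) and over
#' everything, plus the mean raw distances; the per-probe summary used
#' for training trajectories.
#'
#' @param tab a distance table from [distanceTable()].
#' @return list with `byLevel` (data.frame) and overall means
#'   `Rlev`, `Rres`, `Dlev`, `Dres`, `Dsig`.
#' @export
aggregateDistances <- function(tab) {
  byLevel <- do.call(rbind, lapply(split(tab, tab$level), function(d)
    data.frame(level = d$level[1],
               Rlev = mean(d$Rlev, na.rm = TRUE),
               Rres = mean(d$Rres, na.rm = TRUE),
               Dlev = mean(d$Dlev, na.rm = TRUE),
               Dres = mean(d$Dres, na.rm = TRUE),
               Dsig = mean(d$Dsig, na.rm = TRUE))))
  rownames(byLevel) <- NULL
  list(byLevel = byLevel,
       Rlev = mean(tab$Rlev, na.rm = TRUE),
       Rres = mean(tab$Rres, na.rm = TRUE),
       Dlev = mean(tab$Dlev, na.rm = TRUE),
       Dres = mean(tab$Dres, na.rm = TRUE),
       Dsig = mean(tab$Dsig, na.rm = TRUE))
}

#' Correlation between manifold compression and familiarity metrics
#'
#' Pearson correlation and least-squares line between an epoch-indexed
#' series of mean relative distances and a matched series of a
#' familiarity statistic (suppression index or lifetime-sparsity
#' change; the pre-training SI is 0 by convention).
#'
#' @param x,y equal-length numeric series over probe epochs.
#' @return list with `r`, `slope`, `intercept`; all NA with fewer than
#'   3 finite points or a constant series.
#' @export
compressionCorrelation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_))
  fit <- lm(y ~ x)
  list(r = cor(x, y), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]))
}
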