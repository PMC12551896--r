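#' @include linear.R manifold.R runner.R
NULL

#' Full collective-mode analysis of one attractor
#'
#' Convenience pipeline: linearize the circuit around the fixed point of
#' one stimulus, extract gain and collective modes (Gram matrix over the
#' excitatory block, matching the distance metrics), enumerate the
#' signal/level/residual input differences of the stimulus set, and
#' return spectrum, alignments, linearized distances and sensitivities
#' for the top `K` modes.
#'
#' @param conn a [Connectivity-class].
#' @param codes matrix of flattened sparse codes (columns = stimuli).
#' @param info stimulus data.frame (from [stimulusInfo()]).
#' @param stimulus column index of the attractor's stimulus.
#' @param config a [NetworkConfig-class]; defaults to the one in `conn`.
#' @param K number of top collective modes (default 10).
#' @param level restrict input differences to this noise level
#'   (default all noisy levels).
#' @param maxT,tol fixed-point parameters passed to [runToFixedPoint()].
#' @return list with `cms` (the [CollectiveModeSet-class]), `lambda`,
#'   `alignments` (per class), `Dhat` (per class), `RhatLev`, `RhatRes`,
#'   `sensitivities` (per class), `orientation` labels and the
#'   `fixedPoint` record.
#' @export
analyzeAttractor <- function(conn, codes, info, stimulus,
                             config = netConfig(conn), K = 10L,
                             level = NULL, maxT = 3000, tol = 1e-6) {
  fp <- runToFixedPoint(conn, codes[, stimulus], config, maxT, tol,
                        stimulusId = info$stimulusId[stimulus],
                        noiseLevel = info$level[stimulus],
                        sampleIndex = info$sample[stimulus])
  if (!fp@converged)
    stop("attractor did not converge; cannot linearize")
  lin <- linearize(conn, fp, codes[, stimulus])
  gm <- gainModes(lin)
  cms <- collectiveModes(gm, outputIdx = seq_len(lin@nExc),
                         attractorId = fp@stimulusId)
  classes <- c("signal", "level", "residual")
  deltas <- lapply(classes, function(cl)
    inputDeltas(codes, info, cl, level = level))
  names(deltas) <- classes
  K <- min(K, length(cms@lambda))
  align <- lapply(deltas, function(d) modeAlignment(cms, d, K = K))
  Dhat <- vapply(deltas, function(d)
    linearizedDistance(cms, d, K = K), numeric(1))
  gNoise <- (align$level + align$residual) / 2
  lamK <- cms@lambda[seq_len(K)]
  sens <- list(
    signal = modeSensitivities(lamK, align$signal),
    level = modeSensitivities(lamK, align$level),
    residual = modeSensitivities(lamK, align$residual))
  list(cms = cms, lambda = lamK, alignments = align, Dhat = Dhat,
       RhatLev = unname(Dhat["level"] / Dhat["signal"]),
       RhatRes = unname(Dhat["residual"] / Dhat["signal"]),
       sensitivities = sens,
       orientation = classifyOrientation(align$signal, gNoise),
       fixedPoint = fp)
}

#' Write per-neuron familiarity metrics as CSV
#'
#' One row per neuron: suppression index, pre/post lifetime sparsity and
#' peak response between the pre-training probe and the final probe of a
#' protocol run.
#'
#' @param run result of [runFamiliarity()] or [runAssociation()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFamiliarityMetrics <- function(run, path) {
  pre <- SummarizedExperiment::assay(run$probes[[1]]$fpt)
  post <- SummarizedExperiment::assay(
    run$probes[[length(run$probes)]]$fpt)
  si <- suppressionIndex(pre, post)
  tab <- data.frame(
    neuron_id = seq_len(nrow(pre)),
    SI = as.numeric(si),
    S_pre = apply(pre, 1, lifetimeSparsity),
    S_post = apply(post, 1, lifetimeSparsity),
    peak_pre = apply(pre, 1, peakResponse),
    peak_post = apply(post, 1, peakResponse))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write per-probe distance tables as a long-format CSV
#'
#' One row per (probe epoch, noise level, target, sample, metric):
#' columns `epoch`, `level`, `targetId`, `sample`, `metric`, `value`,
#' covering `Dlev`, `Dres`, `Dsig`, `Rlev`, `Rres`.
#'
#' @param run result of [runAssociation()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeDistanceTables <- function(run, path) {
  long <- do.call(rbind, lapply(run$probes, function(p) {
    tab <- suppressMessages(distanceTable(p$fpt))
    do.call(rbind, lapply(c("Dlev", "Dres", "Dsig", "Rlev", "Rres"),
                          function(m)
      data.frame(epoch = p$epoch, level = tab$level,
                 targetId = tab$targetId, sample = tab$sample,
                 metric = m, value = tab[[m]])))
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
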