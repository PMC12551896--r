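#' @include AllClasses.R
NULL

#' Create a plasticity state
#'
#' Bundles the learning-rule choice with its time constants and the
#' per-neuron BCM sliding thresholds. Defaults follow the reference
#' parameterization: synaptic time constant `tauW = 2e9` for both rules
#' and threshold time constant `tauXi = 2e7` for BCM.
#'
#' @param rule `"hebbian"` (general Hebbian rule, relies on weight
#'   normalization for depression) or `"bcm"` (sliding-threshold rule).
#' @param nNeurons number of excitatory neurons (length of `xi`).
#' @param tauW synaptic time constant.
#' @param tauXi BCM threshold time constant.
#' @param xi initial thresholds; default zeros (see [initialThresholds()]
#'   for the recommended initialization from pre-trained responses).
#' @return a [PlasticityState-class].
#' @export
plasticityState <- function(rule = c("hebbian", "bcm"), nNeurons,
                            tauW = 2e9, tauXi = 2e7, xi = NULL) {
  rule <- match.arg(rule)
  if (is.null(xi)) xi <- numeric(nNeurons)
  new("PlasticityState", rule = rule, tauW = tauW, tauXi = tauXi,
      xi = as.numeric(xi))
}

#' BCM weight update
#'
#' `dW[k,l] = (dt/tauW) * r[l] * r[k] * (r[k] - xi[k])` on the masked
#' entries: potentiation when the postsynaptic rate exceeds its sliding
#' threshold, depression below it. Updated weights are clipped at zero
#' from below (E-E synapses stay excitatory).
#'
#' @param Wee E-E weight matrix.
#' @param rE excitatory rates (nonnegative).
#' @param xi per-neuron sliding thresholds.
#' @param dt time step.
#' @param tauW synaptic time constant.
#' @param mask 0/1 support matrix.
#' @return updated weight matrix.
#' @export
bcmUpdate <- function(Wee, rE, xi, dt, tauW, mask) {
  if (any(rE < 0)) stop("contract violation: negative rates")
  W <- Wee + (dt / tauW) * (outer(rE * (rE - xi), rE) * mask)
  pmax(W, 0)
}

#' BCM sliding-threshold update
#'
#' Exponential moving average of the squared firing rate:
#' `xi <- xi + (dt/tauXi) * (-xi + rE^2)`.
#'
#' @inheritParams bcmUpdate
#' @param tauXi threshold time constant.
#' @return updated threshold vector.
#' @export
bcmThresholdUpdate <- function(xi, rE, dt, tauXi) {
  xi + (dt / tauXi) * (-xi + rE^2)
}

#' General Hebbian weight update
#'
#' `dW[k,l] = (dt/tauW) * r[l] * r[k]^2` on the masked entries; always
#' potentiating, with depression delegated to the synaptic-resource
#' normalization (Oja-style synaptic scaling).
#'
#' @inheritParams bcmUpdate
#' @return updated weight matrix.
#' @export
hebbianUpdate <- function(Wee, rE, dt, tauW, mask) {
  Wee + (dt / tauW) * (outer(rE^2, rE) * mask)
}

#' Synaptic-resource normalization
#'
#' Rescales every row of the E-E matrix multiplicatively so that each
#' neuron's total presynaptic weight equals `wTotal`; rows that have
#' decayed to zero are reset to the uniform initial profile
#' `wTotal / |NE(k)|` over the mask.
#'
#' @param Wee E-E weight matrix (nonnegative on the mask).
#' @param wTotal target row sum (the synaptic resource, default 5).
#' @param mask 0/1 support matrix.
#' @return row-normalized weight matrix.
#' @export
normalizeWeights <- function(Wee, wTotal, mask) {
  if (any(Wee < 0)) stop("contract violation: negative weights")
  rs <- rowSums(Wee)
  zero <- rs <= 0
  W <- Wee * (wTotal / ifelse(zero, 1, rs))
  if (any(zero))
    W[zero, ] <- wTotal * mask[zero, , drop = FALSE] /
      rowSums(mask[zero, , drop = FALSE])
  W
}

#' Initial BCM thresholds from pre-trained responses
#'
#' The recommended initialization: each neuron's threshold starts at its
#' average response magnitude across all stimuli and all integration
#' steps of the pre-trained network.
#'
#' @param records list of [FixedPointRecord-class] objects from the
#'   pre-trained network (one per stimulus), or a list of numeric
#'   per-neuron time-averaged rate vectors.
#' @return numeric vector of per-neuron thresholds.
#' @export
initialThresholds <- function(records) {
  means <- lapply(records, function(x)
    if (is(x, "FixedPointRecord")) x@rMean else as.numeric(x))
  Reduce(`+`, means) / length(means)
}
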