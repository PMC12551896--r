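#' @include famcirc-package.R
NULL

#' Convolutional sparse-coding dictionary
#'
#' A set of square filters used to encode images into a sparse
#' feedforward drive. Filters are stored as columns of a matrix with
#' `filterSide^2` rows; after learning each column has unit Euclidean
#' norm. Applied convolutionally with the stored stride and no padding.
#'
#' @slot filters numeric matrix, `filterSide^2 x nFilters`.
#' @slot filterSide integer, filter side length in pixels.
#' @slot stride integer, convolution stride in pixels.
#' @slot seed integer seed used during learning (for provenance).
#' @slot objective numeric, per-iteration learning objective (monitoring).
#' @exportClass SparseDictionary
setClass("SparseDictionary",
  representation(filters = "matrix", filterSide = "integer",
                 stride = "integer", seed = "integer",
                 objective = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@filters) != object@filterSide^2)
      msg <- c(msg, "filters must have filterSide^2 rows")
    if (ncol(object@filters) < 1) msg <- c(msg, "need at least one filter")
    if (any(!is.finite(object@filters))) msg <- c(msg, "non-finite filters")
    if (object@stride < 1) msg <- c(msg, "stride must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Network configuration
#'
#' Geometry, connectivity strengths and integration constants of the
#' hypercolumnar excitatory-inhibitory circuit. One excitatory and one
#' inhibitory neuron per (row, column, channel) triple.
#'
#' @slot nRows,nCols integer hypercolumn grid size.
#' @slot nChannels integer feature channels per hypercolumn.
#' @slot radiusE integer excitatory neighborhood radius (hypercolumns).
#' @slot radiusI integer inhibitory surround radius (hypercolumns).
#' @slot wEE numeric total E-E synaptic resource per neuron.
#' @slot wIE numeric total E-I strength per inhibitory neuron.
#' @slot tauE,tauI numeric membrane time constants (time units).
#' @slot dt numeric Euler integration step (time units).
#' @slot inputScale numeric multiplier applied to the sparse code drive.
#' @slot divergenceBound numeric rate bound above which integration aborts.
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(nRows = "integer", nCols = "integer", nChannels = "integer",
                 radiusE = "integer", radiusI = "integer",
                 wEE = "numeric", wIE = "numeric",
                 tauE = "numeric", tauI = "numeric", dt = "numeric",
                 inputScale = "numeric", divergenceBound = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nRows < 1 || object@nCols < 1) msg <- c(msg, "grid must be >= 1x1")
    if (object@nChannels < 1) msg <- c(msg, "nChannels must be >= 1")
    if (object@radiusE < 0 || object@radiusI < 0) msg <- c(msg, "radii must be >= 0")
    if (object@tauE <= 0 || object@tauI <= 0 || object@dt <= 0)
      msg <- c(msg, "tauE, tauI and dt must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Circuit connectivity
#'
#' Weight matrices over the flattened neuron index (channel fastest, then
#' column, then row). `Wee` is the plastic excitatory-excitatory matrix
#' with support mask `mask`; `Wie` (E to I) and `Wei` (I to E) are fixed.
#'
#' @slot Wee numeric `Ne x Ne` nonnegative matrix (plastic).
#' @slot Wei numeric `Ne x Ni` nonpositive matrix (fixed, uniform -1/Ni).
#' @slot Wie numeric `Ni x Ne` nonnegative matrix (fixed).
#' @slot mask numeric 0/1 `Ne x Ne` support matrix for `Wee`.
#' @slot config the [NetworkConfig-class] that generated the geometry.
#' @exportClass Connectivity
setClass("Connectivity",
  representation(Wee = "matrix", Wei = "matrix", Wie = "matrix",
                 mask = "matrix", config = "NetworkConfig"),
  validity = function(object) {
    msg <- NULL
    ne <- nrow(object@Wee)
    if (ncol(object@Wee) != ne) msg <- c(msg, "Wee must be square")
    if (!all(dim(object@mask) == dim(object@Wee)))
      msg <- c(msg, "mask must match Wee")
    if (any(object@Wee[object@mask == 0] != 0))
      msg <- c(msg, "Wee has support outside its mask")
    if (any(object@Wee < 0)) msg <- c(msg, "Wee must be nonnegative")
    if (any(object@Wei > 0)) msg <- c(msg, "Wei must be nonpositive")
    if (any(object@Wie < 0)) msg <- c(msg, "Wie must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' Steady-state record for one stimulus
#'
#' Result of integrating the circuit from the zero state under a fixed
#' drive until convergence. `rStar` is the excitatory steady state
#' (time-average over the final averaging window).
#'
#' @slot stimulusId character stimulus label.
#' @slot noiseLevel numeric occlusion fraction (0 for clean targets).
#' @slot sampleIndex integer noise-sample index (0 for clean targets).
#' @slot rStar numeric excitatory steady-state rates.
#' @slot riStar numeric inhibitory steady-state rates.
#' @slot residual numeric final max-norm step change.
#' @slot converged logical convergence flag.
#' @slot steps integer number of Euler steps taken.
#' @slot popTrace numeric mean excitatory population rate per step.
#' @slot rMean numeric per-neuron time-averaged excitatory rate over the
#'   whole run (used to initialize BCM thresholds).
#' @exportClass FixedPointRecord
setClass("FixedPointRecord",
  representation(stimulusId = "character", noiseLevel = "numeric",
                 sampleIndex = "integer", rStar = "numeric",
                 riStar = "numeric", residual = "numeric",
                 converged = "logical", steps = "integer",
                 popTrace = "numeric", rMean = "numeric"))

#' Stimulus set
#'
#' An enumerable collection of grayscale stimuli: clean targets plus,
#' optionally, occluded variants at fixed noise levels. Enumeration
#' order is stable and seed-independent.
#'
#' @slot stimuli list; each element has `pixels` (side x side matrix in
#'   \[0,1\]), `targetId`, `level`, `sample`, `seed`.
#' @slot side integer image side in pixels.
#' @slot levels numeric occlusion levels represented (excluding 0).
#' @slot samplesPerLevel integer samples per (target, level).
#' @exportClass StimulusSet
setClass("StimulusSet",
  representation(stimuli = "list", side = "integer",
                 levels = "numeric", samplesPerLevel = "integer"),
  validity = function(object) {
    ok <- vapply(object@stimuli, function(s)
      is.matrix(s$pixels) && all(dim(s$pixels) == object@side) &&
        all(is.finite(s$pixels)) && min(s$pixels) >= 0 && max(s$pixels) <= 1,
      logical(1))
    if (all(ok)) TRUE else "stimulus pixels must be side x side in [0,1]"
  })

#' Plasticity state
#'
#' Learning-rule selection and constants, plus the per-neuron BCM sliding
#' thresholds (unused under the general Hebbian rule).
#'
#' @slot rule character, `"hebbian"` or `"bcm"`.
#' @slot tauW numeric synaptic time constant.
#' @slot tauXi numeric BCM threshold time constant.
#' @slot xi numeric per-neuron thresholds (squared-rate units).
#' @exportClass PlasticityState
setClass("PlasticityState",
  representation(rule = "character", tauW = "numeric",
                 tauXi = "numeric", xi = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@rule %in% c("hebbian", "bcm"))
      msg <- c(msg, "rule must be 'hebbian' or 'bcm'")
    if (any(object@xi < 0)) msg <- c(msg, "xi must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Linearization of the circuit around an attractor
#'
#' First-order expansion of the stacked (excitatory + inhibitory)
#' fixed-point map: diagonal local sensitivities `sigmaPrime`, recurrent
#' gain matrix `M = (I - S'W)^-1` and Jacobian `J = M S'` of the steady
#' state with respect to the feedforward drive.
#'
#' @slot sigmaPrime numeric vector of local sensitivities.
#' @slot M numeric recurrent gain matrix.
#' @slot J numeric Jacobian matrix.
#' @slot rStar numeric stacked fixed point `c(re, ri)`.
#' @slot nExc integer size of the excitatory block.
#' @slot attractorId character label.
#' @exportClass Linearization
setClass("Linearization",
  representation(sigmaPrime = "numeric", M = "matrix", J = "matrix",
                 rStar = "numeric", nExc = "integer",
                 attractorId = "character"))

setMethod("show", "Linearization", function(object) {
  cat(sprintf("Linearization of '%s': %d states (%d excitatory)\n",
              object@attractorId, length(object@rStar), object@nExc))
})

#' Recurrent gain modes
#'
#' Eigendecomposition of the recurrent gain matrix `M = (I - S'W)^-1`:
#' eigenvalues `mu`, right eigenvectors (columns of `Wright`), left
#' eigenvectors (columns of `Vleft`, scaled so `t(Vleft) %*% Wright = I`)
#' and the effective input filters `Vtilde = S' Vleft`.
#'
#' @slot mu complex eigenvalues of the gain matrix.
#' @slot Wright,Vleft,Vtilde complex matrices of mode vectors (columns).
#' @slot defective logical, TRUE when the eigenbasis was ill-conditioned
#'   and a regularized inverse was used for the left vectors.
#' @exportClass GainModeSet
setClass("GainModeSet",
  representation(mu = "complex", Wright = "matrix", Vleft = "matrix",
                 Vtilde = "matrix", defective = "logical"))

#' Collective modes of the linearized circuit
#'
#' Orthogonal modes diagonalizing the Gram matrix of the gain-mode output
#' patterns. `lambda` is the (real, nonnegative) spectrum, columns of `Q`
#' the Gram eigenvectors, columns of `Phi` the effective input filters
#' `phi_k`; the squared linear response distance decomposes as
#' `sum_k lambda_k |phi_k^H dalpha|^2`.
#'
#' @slot lambda numeric spectrum, sorted descending.
#' @slot Q complex matrix of Gram eigenvectors (columns).
#' @slot Phi complex matrix of effective input filters (columns).
#' @slot attractorId character label of the linearized attractor.
#' @exportClass CollectiveModeSet
setClass("CollectiveModeSet",
  representation(lambda = "numeric", Q = "matrix", Phi = "matrix",
                 attractorId = "character"),
  validity = function(object) {
    if (any(object@lambda < -1e-8)) "lambda must be nonnegative" else TRUE
  })

setMethod("show", "SparseDictionary", function(object) {
  cat(sprintf("SparseDictionary: %d filters of %dx%d, stride %d\n",
              ncol(object@filters), object@filterSide, object@filterSide,
              object@stride))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf(
    "NetworkConfig: %dx%d hypercolumns x %d channels (%d E + %d I neurons)\n",
    object@nRows, object@nCols, object@nChannels,
    object@nRows * object@nCols * object@nChannels,
    object@nRows * object@nCols * object@nChannels))
  cat(sprintf("  Re=%d Ri=%d wEE=%g wIE=%g tauE=%g tauI=%g dt=%g scale=%g\n",
              object@radiusE, object@radiusI, object@wEE, object@wIE,
              object@tauE, object@tauI, object@dt, object@inputScale))
})

setMethod("show", "Connectivity", function(object) {
  cat(sprintf("Connectivity: %d E neurons, %d plastic E-E synapses\n",
              nrow(object@Wee), sum(object@mask > 0)))
})

setMethod("show", "StimulusSet", function(object) {
  cat(sprintf("StimulusSet: %d stimuli (%dx%d px), levels {%s}, %d samples/level\n",
              length(object@stimuli), object@side, object@side,
              paste(object@levels, collapse = ", "),
              object@samplesPerLevel))
})

setMethod("show", "CollectiveModeSet", function(object) {
  cat(sprintf("CollectiveModeSet: %d modes, top spectrum %s\n",
              length(object@lambda),
              paste(signif(head(object@lambda, 3), 3), collapse = ", ")))
})
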