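#' @include AllClasses.R utils.R
NULL

#' Construct a network configuration
#'
#' Defaults reproduce the reference circuit: an 8 x 8 grid of
#' hypercolumns with 64 feature channels each (4096 excitatory and 4096
#' inhibitory neurons), excitatory neighborhood radius 2, inhibitory
#' surround radius 1, total E-E resource `wEE = 5`, excitatory/inhibitory
#' time constants 40 and 20 time units, Euler step 1, and a x30 drive
#' scale. `wIE` is experiment specific (20 for familiarity training on
#' clean images, 30 for the association protocol with occluded variants).
#'
#' @param nRows,nCols hypercolumn grid size.
#' @param nChannels feature channels per hypercolumn.
#' @param radiusE excitatory neighborhood radius in hypercolumns.
#' @param radiusI inhibitory surround radius in hypercolumns.
#' @param wEE total E-E synaptic resource per excitatory neuron.
#' @param wIE total E-I strength per inhibitory neuron.
#' @param tauE,tauI membrane time constants (time units).
#' @param dt Euler integration step (time units).
#' @param inputScale multiplier applied to the sparse-code drive.
#' @param divergenceBound rate bound above which integration aborts.
#' @return a [NetworkConfig-class].
#' @export
networkConfig <- function(nRows = 8L, nCols = 8L, nChannels = 64L,
                          radiusE = 2L, radiusI = 1L,
                          wEE = 5, wIE = 20, tauE = 40, tauI = 20,
                          dt = 1, inputScale = 30,
                          divergenceBound = 1e6) {
  if (nChannels == 0) stop("nChannels must be >= 1")
  if (radiusE >= max(nRows, nCols) || radiusI >= max(nRows, nCols))
    warning("neighborhood radius saturates the grid; neighborhoods clip")
  new("NetworkConfig", nRows = as.integer(nRows), nCols = as.integer(nCols),
      nChannels = as.integer(nChannels), radiusE = as.integer(radiusE),
      radiusI = as.integer(radiusI), wEE = wEE, wIE = wIE,
      tauE = tauE, tauI = tauI, dt = dt, inputScale = inputScale,
      divergenceBound = divergenceBound)
}

#' Map (row, column, channel) to the flat neuron index and back
#'
#' The flat ordering is channel fastest, then grid column, then grid
#' row, matching [flattenCode()].
#'
#' @param r,c,d 1-based grid row, grid column, channel.
#' @param k 1-based flat index.
#' @param config a [NetworkConfig-class].
#' @return `flattenIndex`: integer flat index; `unflattenIndex`: integer
#'   vector `c(r, c, d)`.
#' @export
flattenIndex <- function(r, c, d, config) {
  ((r - 1L) * config@nCols + (c - 1L)) * config@nChannels + d
}

#' @rdname flattenIndex
#' @export
unflattenIndex <- function(k, config) {
  k0 <- k - 1L
  d <- k0 %% config@nChannels
  h <- k0 %/% config@nChannels
  c(h %/% config@nCols + 1L, h %% config@nCols + 1L, d + 1L)
}

# spatial hypercolumn adjacency (within Chebyshev radius), clipped at borders
spatialAdjacency <- function(nRows, nCols, radius) {
  rr <- rep(seq_len(nRows), each = nCols)
  cc <- rep(seq_len(nCols), nRows)
  outer(seq_along(rr), seq_along(rr), function(i, j)
    as.numeric(abs(rr[i] - rr[j]) <= radius & abs(cc[i] - cc[j]) <= radius))
}

#' Build the hypercolumnar E-I connectivity
#'
#' Every excitatory neuron receives plastic E-E projections from all
#' channels of the hypercolumns within its excitatory neighborhood
#' (Chebyshev radius `radiusE`, clipped at the grid borders), with the
#' total resource `wEE` spread uniformly over the actual neighborhood.
#' Every inhibitory neuron receives fixed E-I projections from the
#' same-channel neurons within radius `radiusI` (surround suppression)
#' plus the other channels of its own hypercolumn (divisive
#' normalization), with total strength `wIE` spread uniformly; it
#' projects back to all excitatory neurons with weight `-1/Ni`.
#'
#' @param config a [NetworkConfig-class].
#' @return a [Connectivity-class].
#' @export
buildConnectivity <- function(config) {
  nd <- config@nChannels
  nh <- config@nRows * config@nCols
  ne <- nh * nd
  Se <- spatialAdjacency(config@nRows, config@nCols, config@radiusE)
  mask <- kronecker(Se, matrix(1, nd, nd))
  Wee <- config@wEE * mask / rowSums(mask)

  Si <- spatialAdjacency(config@nRows, config@nCols, config@radiusI)
  supIE <- kronecker(Si, diag(nd)) +
    kronecker(diag(nh), matrix(1, nd, nd) - diag(nd))
  Wie <- config@wIE * supIE / rowSums(supIE)
  Wei <- matrix(-1 / ne, ne, ne)

  new("Connectivity", Wee = Wee, Wei = Wei, Wie = Wie, mask = mask,
      config = config)
}

#' Neighborhood sizes per neuron
#'
#' Actual (border-clipped) excitatory and inhibitory presynaptic
#' neighborhood sizes; for interior neurons these equal
#' `nChannels * (2*radiusE + 1)^2` and `(2*radiusI + 1)^2 + nChannels - 1`.
#'
#' @param conn a [Connectivity-class].
#' @return list with integer vectors `NE` and `NI`.
#' @export
neighborhoodSizes <- function(conn) {
  list(NE = as.integer(round(rowSums(conn@mask))),
       NI = as.integer(round(rowSums(conn@Wie > 0))))
}

#' Squared rectified-linear activation and its derivative
#'
#' The circuit's pointwise nonlinearity `sigma(z) = max(z, 0)^2` and its
#' derivative `sigma'(z) = 2 * max(z, 0)`.
#'
#' @param z net synaptic input (any numeric shape).
#' @return rates (or local sensitivities) of the same shape.
#' @export
activation <- function(z) pmax(z, 0)^2

#' @rdname activation
#' @export
activationDeriv <- function(z) 2 * pmax(z, 0)

#' One forward-Euler step of the rate dynamics
#'
#' Reference (pure R) implementation of the coupled E-I update:
#' `re <- re + dt/tauE * (-re + sigma(Wee re + Wei ri + alpha))` and
#' `ri <- ri + dt/tauI * (-ri + sigma(Wie re))`, the inhibitory equation
#' using the pre-update excitatory rates. The compiled integration loops
#' follow these semantics exactly.
#'
#' @param state list with numeric vectors `re` and `ri`.
#' @param conn a [Connectivity-class].
#' @param alpha feedforward drive vector (flat neuron order).
#' @param config a [NetworkConfig-class]; defaults to the one in `conn`.
#' @return updated state list.
#' @export
stepNetwork <- function(state, conn, alpha, config = netConfig(conn)) {
  ze <- conn@Wee %*% state$re + conn@Wei %*% state$ri + alpha
  reNew <- state$re + (config@dt / config@tauE) * (-state$re + activation(ze))
  zi <- conn@Wie %*% state$re
  riNew <- state$ri + (config@dt / config@tauI) * (-state$ri + activation(zi))
  if (any(reNew > config@divergenceBound))
    stop("instability: excitatory rates exceeded the divergence bound")
  if (any(riNew > config@divergenceBound))
    stop("instability: inhibitory rates exceeded the divergence bound")
  list(re = as.numeric(reNew), ri = as.numeric(riNew))
}

#' Integrate the circuit to a stimulus-specific fixed point
#'
#' Resets the state to zero, integrates the rate dynamics under a fixed
#' drive until the max-norm step change stays below `tol` for 20
#' consecutive time units (or `maxT` is reached), and reports the
#' steady state as the time-average of the final 20 time units.
#'
#' @param conn a [Connectivity-class].
#' @param alpha feedforward drive vector (flat neuron order).
#' @param config a [NetworkConfig-class]; defaults to the one in `conn`.
#' @param maxT maximum integration time (time units, default 1000).
#' @param tol convergence tolerance on the max-norm step change.
#' @param stimulusId,noiseLevel,sampleIndex labels stored in the record.
#' @return a [FixedPointRecord-class]; `converged` is FALSE when `maxT`
#'   was reached first. Diverging rates raise an instability error.
#' @export
runToFixedPoint <- function(conn, alpha, config = netConfig(conn),
                            maxT = 1000, tol = 1e-6,
                            stimulusId = "", noiseLevel = 0,
                            sampleIndex = 0L) {
  win <- max(1L, as.integer(round(20 / config@dt)))
  res <- cpp_fixed_point(conn@Wee, conn@Wei, conn@Wie, as.numeric(alpha),
                         config@tauE, config@tauI, config@dt,
                         as.integer(round(maxT / config@dt)), tol,
                         win, win, config@divergenceBound)
  if (res$diverged == 1)
    stop("instability: excitatory rates exceeded the divergence bound")
  if (res$diverged == 2)
    stop("instability: inhibitory rates exceeded the divergence bound")
  new("FixedPointRecord", stimulusId = as.character(stimulusId),
      noiseLevel = as.numeric(noiseLevel),
      sampleIndex = as.integer(sampleIndex),
      rStar = as.numeric(res$re_star), riStar = as.numeric(res$ri_star),
      residual = as.numeric(res$residual),
      converged = as.logical(res$converged),
      steps = as.integer(res$steps), popTrace = as.numeric(res$pop_trace),
      rMean = as.numeric(res$re_mean))
}
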