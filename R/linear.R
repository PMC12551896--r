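#' @include AllClasses.R circuit.R
NULL

#' Linearize the circuit around a converged attractor
#'
#' Builds the stacked state `r = c(re, ri)` and block connectivity
#' `W = [Wee, Wei; Wie, 0]`, evaluates the local sensitivities
#' `sigma'(W r* + alpha)` and forms the recurrent gain matrix
#' `M = (I - S'W)^-1` and Jacobian `J = M S'`, which maps a feedforward
#' perturbation (stacked, with zeros on the inhibitory block) to the
#' first-order shift of the fixed point.
#'
#' @param conn a [Connectivity-class].
#' @param fp a converged [FixedPointRecord-class].
#' @param alpha the feedforward drive the fixed point was computed for
#'   (flat excitatory order).
#' @param condLimit condition-number limit; above it an
#'   ill-conditioned-linearization error is raised (default 1e12).
#' @return a [Linearization-class].
#' @export
linearize <- function(conn, fp, alpha, condLimit = 1e12) {
  ne <- length(fp@rStar)
  ni <- length(fp@riStar)
  W <- rbind(cbind(conn@Wee, conn@Wei),
             cbind(conn@Wie, matrix(0, ni, ni)))
  r <- c(fp@rStar, fp@riStar)
  net <- as.numeric(W %*% r) + c(as.numeric(alpha), numeric(ni))
  sp <- activationDeriv(net)
  A <- diag(ne + ni) - sp * W  # diag(sp) %*% W
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1 / condLimit)
    stop("ill-conditioned linearization: (I - S'W) has condition number > ",
         format(condLimit))
  M <- solve(A)
  J <- sweep(M, 2, sp, "*")
  new("Linearization", sigmaPrime = sp, M = M, J = J, rStar = r,
      nExc = as.integer(ne), attractorId = fp@stimulusId)
}

#' Eigenmodes of the recurrent gain matrix
#'
#' Full eigendecomposition `M = sum_i mu_i w_i v_i^T` with right
#' eigenvectors `w_i`, left eigenvectors `v_i` scaled to
#' biorthonormality (`v_i^T w_j = delta_ij`), and effective input
#' filters `vtilde_i = S' v_i`. Complex conjugate pairs are kept in
#' complex arithmetic. When the eigenvector basis is numerically
#' defective the left vectors come from a tolerance-truncated
#' pseudoinverse and the result is flagged.
#'
#' @param lin a [Linearization-class].
#' @return a [GainModeSet-class].
#' @export
gainModes <- function(lin) {
  e <- eigen(lin@M)
  Wr <- e$vectors + 0i
  mu <- e$values + 0i
  sv <- svd(Wr)$d
  defective <- min(sv) / max(sv) < 1e-12
  Vl <- if (defective) {
    s <- svd(Wr)
    keep <- s$d > max(s$d) * 1e-12
    t(Conj(s$v[, keep, drop = FALSE] %*%
             (t(Conj(s$u[, keep, drop = FALSE])) / s$d[keep])))
  } else {
    t(solve(Wr))
  }
  if (defective)
    message("gain-mode basis numerically defective; ",
            "using regularized left eigenvectors")
  Vt <- lin@sigmaPrime * Vl
  new("GainModeSet", mu = mu, Wright = Wr, Vleft = Vl, Vtilde = Vt,
      defective = defective)
}

#' Collective modes of the linearized response geometry
#'
#' Diagonalizes the (Hermitian, positive semidefinite) Gram matrix of
#' the gain-mode output patterns, optionally projected onto a subset of
#' output coordinates (by default the excitatory block is used when
#' `outputIdx` is given by the caller; all coordinates otherwise). The
#' spectrum `lambda_k` and effective input filters `phi_k` decompose
#' the squared linear response distance exactly at full rank:
#' `||P J dalpha||^2 = sum_k lambda_k |phi_k^H dalpha_stacked|^2`.
#'
#' @param gm a [GainModeSet-class].
#' @param outputIdx indices of the output coordinates entering the
#'   distance (e.g. `1:nExc` for excitatory-only distances); default all.
#' @param attractorId label stored with the result.
#' @return a [CollectiveModeSet-class], modes sorted by decreasing
#'   spectrum.
#' @export
collectiveModes <- function(gm, outputIdx = NULL, attractorId = "") {
  Wo <- if (is.null(outputIdx)) gm@Wright else gm@Wright[outputIdx, , drop = FALSE]
  G <- Conj(t(Wo)) %*% Wo
  G <- (G + Conj(t(G))) / 2
  eg <- eigen(G, symmetric = TRUE)
  lambda <- pmax(Re(eg$values), 0)
  Q <- eg$vectors + 0i
  Phi <- gm@Vtilde %*% (gm@mu * Conj(Q))
  new("CollectiveModeSet", lambda = lambda, Q = Q, Phi = Phi,
      attractorId = as.character(attractorId))
}

#' Input-difference vectors by distance class
#'
#' Unit-normalized sparse-code differences over the same stimulus
#' pairings as the manifold distances: `"signal"` pairs samples with
#' the other targets at the same level, `"level"` with the same target
#' at the adjacent lower level, `"residual"` with the same target and
#' level. Zero differences are dropped.
#'
#' @param codes matrix of flattened sparse codes, one column per
#'   stimulus.
#' @param info data.frame with columns `targetId`, `level`, `sample`
#'   aligned with the columns of `codes` (e.g. from [stimulusInfo()]).
#' @param directionClass one of `"signal"`, `"level"`, `"residual"`.
#' @param level restrict to pairs whose reference sample sits at this
#'   noise level (default: all levels > 0).
#' @return matrix of unit column vectors (one per pair).
#' @export
inputDeltas <- function(codes, info,
                        directionClass = c("signal", "level", "residual"),
                        level = NULL) {
  directionClass <- match.arg(directionClass)
  low <- lowerLevel(info$level)
  rows <- which(info$level > 0)
  if (!is.null(level)) rows <- rows[info$level[rows] %in% level]
  pairs <- list()
  seen <- character(0)
  addPair <- function(i, j) {
    key <- paste(sort(c(i, j)), collapse = "-")
    if (!key %in% seen) {
      seen <<- c(seen, key)
      pairs[[length(pairs) + 1L]] <<- c(i, j)
    }
  }
  for (i in rows) {
    n <- info$level[i]; l <- info$targetId[i]
    j <- switch(directionClass,
      signal = which(info$targetId != l & info$level == n),
      level = which(info$targetId == l & info$level == low(n)),
      residual = which(info$targetId == l & info$level == n &
                         seq_len(nrow(info)) != i))
    for (jj in j) addPair(i, jj)
  }
  if (length(pairs) == 0) stop("data error: empty direction class")
  out <- vapply(pairs, function(p) {
    d <- codes[, p[1]] - codes[, p[2]]
    nrm <- sqrt(sum(d^2))
    if (nrm > 0) d / nrm else rep(NA_real_, length(d))
  }, numeric(nrow(codes)))
  out <- out[, colSums(is.na(out)) == 0, drop = FALSE]
  if (ncol(out) == 0) stop("data error: all pairs had zero difference")
  out
}

#' Linearized distance carried by the top collective modes
#'
#' Mean over the difference vectors of
#' `sum_{k<=K} lambda_k |phi_k^H dalpha|^2`; with `K` at full rank this
#' equals the mean squared linearized response distance.
#'
#' @param cms a [CollectiveModeSet-class].
#' @param deltas matrix of unit input differences (columns), living on
#'   the input coordinates `inputIdx` of the stacked system.
#' @param K number of top modes (default 10).
#' @param inputIdx rows of the stacked input the deltas address
#'   (default the leading `nrow(deltas)` rows, i.e. the excitatory
#'   block).
#' @return the mean linearized squared distance.
#' @export
linearizedDistance <- function(cms, deltas, K = 10L,
                               inputIdx = seq_len(nrow(deltas))) {
  K <- min(K, length(cms@lambda))
  proj <- Conj(t(cms@Phi[inputIdx, seq_len(K), drop = FALSE])) %*% deltas
  mean(colSums(cms@lambda[seq_len(K)] * abs(proj)^2))
}

#' Mode alignments with an input-variation covariance
#'
#' `g_k = Re(phi_k^H C phi_k)` for the covariance
#' `C = <dalpha dalpha^T>` of a class of unit input differences;
#' nonnegative for positive semidefinite `C`.
#'
#' @param cms a [CollectiveModeSet-class].
#' @param C input covariance matrix on the input coordinates
#'   `inputIdx`, or a matrix of unit difference columns from which the
#'   covariance is formed.
#' @param K number of top modes (default all).
#' @param inputIdx rows of the stacked input addressed by `C`.
#' @param isDeltas treat `C` as difference columns (default TRUE when
#'   `C` is not square).
#' @return numeric vector of alignments `g_k`.
#' @export
modeAlignment <- function(cms, C, K = length(cms@lambda),
                          inputIdx = seq_len(nrow(C)),
                          isDeltas = nrow(C) != ncol(C)) {
  if (isDeltas) C <- C %*% t(C) / ncol(C)
  K <- min(K, length(cms@lambda))
  Phi <- cms@Phi[inputIdx, seq_len(K), drop = FALSE]
  Re(colSums(Conj(Phi) * (C %*% Phi)))
}

#' Classify collective modes as signal- or noise-oriented
#'
#' A mode is signal-oriented when its pre-training signal alignment
#' exceeds its noise alignment (the average of the level and residual
#' alignments) by more than `threshold` times the maximum absolute
#' difference across modes, noise-oriented in the reverse case, and
#' neutral otherwise (including when all differences vanish).
#'
#' @param gSignal,gNoise pre-training alignments per mode.
#' @param threshold fraction of the maximum difference (default 0.1).
#' @return character vector of `"signal"`, `"noise"`, `"neutral"`.
#' @export
classifyOrientation <- function(gSignal, gNoise, threshold = 0.1) {
  d <- gSignal - gNoise
  m <- max(abs(d))
  if (m == 0) return(rep("neutral", length(d)))
  ifelse(d > threshold * m, "signal",
         ifelse(d < -threshold * m, "noise", "neutral"))
}

# greedy mode correspondence by normalized |phi_pre^H phi_post| overlap
matchModes <- function(pre, post, K) {
  P1 <- pre@Phi[, seq_len(K), drop = FALSE]
  P2 <- post@Phi[, seq_len(K), drop = FALSE]
  n1 <- sqrt(Re(colSums(Conj(P1) * P1)))
  n2 <- sqrt(Re(colSums(Conj(P2) * P2)))
  ov <- abs(Conj(t(P1)) %*% P2) / pmax(n1 %o% n2, 1e-300)
  match <- rep(NA_integer_, K)
  for (step in seq_len(K)) {
    b <- which(ov == max(ov), arr.ind = TRUE)[1, ]
    match[b[1]] <- b[2]
    ov[b[1], ] <- -Inf
    ov[, b[2]] <- -Inf
  }
  match
}

#' Pre/post changes of collective-mode spectrum and alignments
#'
#' Matches the top-`K` modes across training (greedily by input-filter
#' overlap, or by spectral rank), computes the per-mode spectrum change
#' and alignment changes for each direction class, max-normalizes the
#' magnitudes, labels each mode's pre-training orientation, and flags
#' the modes whose change magnitude exceeds `inclusionThreshold` times
#' the maximum change.
#'
#' @param pre,post [CollectiveModeSet-class] objects for the same
#'   attractor before and after training.
#' @param alignPre,alignPost named lists with numeric per-mode
#'   alignments `signal`, `level`, `residual` (computed with
#'   [modeAlignment()] on the respective mode sets).
#' @param K number of top modes to analyse (default 10).
#' @param inclusionThreshold fraction of the maximum change magnitude
#'   below which a mode is excluded from density summaries (default
#'   0.1).
#' @param matching `"filter"` (default) or `"rank"`.
#' @return data.frame with per-mode `dLambda`, `dgSignal`, `dgLevel`,
#'   `dgResidual`, `dgNoise`, their max-normalized versions, the
#'   orientation label and inclusion flags.
#' @export
modeChangeStats <- function(pre, post, alignPre, alignPost, K = 10L,
                            inclusionThreshold = 0.1,
                            matching = c("filter", "rank")) {
  matching <- match.arg(matching)
  K <- min(K, length(pre@lambda), length(post@lambda))
  map <- if (matching == "rank") seq_len(K) else matchModes(pre, post, K)
  dLambda <- post@lambda[map] - pre@lambda[seq_len(K)]
  gN <- function(a) (a$level + a$residual) / 2
  dgSignal <- alignPost$signal[map] - alignPre$signal[seq_len(K)]
  dgLevel <- alignPost$level[map] - alignPre$level[seq_len(K)]
  dgResidual <- alignPost$residual[map] - alignPre$residual[seq_len(K)]
  dgNoise <- gN(alignPost)[map] - gN(alignPre)[seq_len(K)]
  nrm <- function(x) if (max(abs(x)) > 0) x / max(abs(x)) else x
  orient <- classifyOrientation(alignPre$signal[seq_len(K)],
                                gN(alignPre)[seq_len(K)])
  inc <- function(x) abs(x) > inclusionThreshold * max(abs(x))
  data.frame(mode = seq_len(K), matched = map,
             dLambda = dLambda, dgSignal = dgSignal, dgLevel = dgLevel,
             dgResidual = dgResidual, dgNoise = dgNoise,
             dLambdaNorm = nrm(dLambda), dgSignalNorm = nrm(dgSignal),
             dgNoiseNorm = nrm(dgNoise), orientation = orient,
             includedLambda = inc(dLambda), includedG = inc(dgSignal),
             stringsAsFactors = FALSE)
}

#' Sensitivities of the fractional linear distance to mode changes
#'
#' With the linear distance `D = sum_k lambda_k g_k`, the sensitivity
#' of the fractional change `Dtilde = dD / D_pre` to a spectrum change
#' of mode `k` is `g_k,pre / sum_j lambda_j,pre g_j,pre`, and to an
#' alignment change `lambda_k,pre / sum_j lambda_j,pre g_j,pre`. The
#' weighted sums `sum_k lambda_k,pre * dDtilde/dLambda_k` and
#' `sum_k g_k,pre * dDtilde/dg_k` both equal 1.
#'
#' @param lambdaPre pre-training spectrum over the analysed modes.
#' @param gPre matching pre-training alignments.
#' @return list with `dLambda` and `dG` sensitivity vectors (NA when
#'   the pre-training distance is zero).
#' @export
modeSensitivities <- function(lambdaPre, gPre) {
  den <- sum(lambdaPre * gPre)
  if (den == 0)
    return(list(dLambda = rep(NA_real_, length(lambdaPre)),
                dG = rep(NA_real_, length(gPre))))
  list(dLambda = gPre / den, dG = lambdaPre / den)
}

#' First-order compression condition
#'
#' Taylor expansion of the relative distance `R = Dnoise / Dsig` around
#' the pre-training state:
#' `dR ~ (Dsig_pre * dDnoise - Dnoise_pre * dDsig) / Dsig_pre^2`.
#' Compression (`dR < 0`) holds exactly when the fractional signal
#' change exceeds the fractional noise change.
#'
#' @param DsigPre,DnoisePre pre-training distances (> 0).
#' @param DsigPost,DnoisePost post-training distances.
#' @return list with `deltaR` (first-order), `DtildeSig`,
#'   `DtildeNoise` (fractional changes) and logical `compresses`.
#' @export
compressionCondition <- function(DsigPre, DnoisePre, DsigPost, DnoisePost) {
  dSig <- DsigPost - DsigPre
  dNoise <- DnoisePost - DnoisePre
  deltaR <- (DsigPre * dNoise - DnoisePre * dSig) / DsigPre^2
  list(deltaR = deltaR, DtildeSig = dSig / DsigPre,
       DtildeNoise = dNoise / DnoisePre,
       compresses = dSig / DsigPre > dNoise / DnoisePre)
}
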