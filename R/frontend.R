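#' @include AllClasses.R utils.R
NULL

#' Feature-map grid produced by valid strided convolution
#'
#' Number of filter placements per side when convolving a square image
#' with a square filter at a given stride and no padding. The default
#' configuration (32 px image, 9 px filters, stride 3) yields an 8 x 8
#' grid of hypercolumns.
#'
#' @param imageSide image side length in pixels.
#' @param filterSide filter side length in pixels.
#' @param stride stride in pixels (>= 1).
#' @return integer vector `c(nRows, nCols)` of the feature-map grid.
#' @examples
#' convGridShape(32, 9, 3)  # 8 8
#' @export
convGridShape <- function(imageSide, filterSide, stride) {
  if (filterSide > imageSide)
    stop("invalid geometry: filter (", filterSide,
         " px) larger than image (", imageSide, " px)")
  if (stride < 1) stop("stride must be >= 1")
  n <- floor((imageSide - filterSide) / stride) + 1L
  c(as.integer(n), as.integer(n))
}

# 1-based top-left pixel offsets of every filter placement along one side
convOffsets <- function(imageSide, filterSide, stride) {
  n <- convGridShape(imageSide, filterSide, stride)[1]
  1L + stride * (seq_len(n) - 1L)
}

# Extract all stride-aligned patches of `image` as rows of a matrix.
# Row order matches the hypercolumn order: grid row major, i.e. position
# (r, c) maps to row (r-1)*nCols + c.
extractPatches <- function(image, filterSide, stride) {
  offs <- convOffsets(nrow(image), filterSide, stride)
  n <- length(offs)
  out <- matrix(0, n * n, filterSide^2)
  idx <- 1L
  for (r in offs) for (cc in offs) {
    out[idx, ] <- as.vector(image[r:(r + filterSide - 1L),
                                  cc:(cc + filterSide - 1L)])
    idx <- idx + 1L
  }
  out
}

# Adjoint of extractPatches composed with the dictionary: overlap-add the
# per-position reconstructions D %*% a into an image canvas.
overlapAdd <- function(coefRows, dict, imageSide) {
  f <- dict@filterSide
  offs <- convOffsets(imageSide, f, dict@stride)
  recon <- matrix(0, imageSide, imageSide)
  patches <- coefRows %*% t(dict@filters)  # nPos x f^2
  idx <- 1L
  for (r in offs) for (cc in offs) {
    recon[r:(r + f - 1L), cc:(cc + f - 1L)] <-
      recon[r:(r + f - 1L), cc:(cc + f - 1L)] +
      matrix(patches[idx, ], f, f)
    idx <- idx + 1L
  }
  recon
}

softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Largest eigenvalue of the composed operator a -> D^T patches(overlapAdd(a))
# by power iteration; Lipschitz constant of the smooth ISTA term.
convLipschitz <- function(dict, imageSide, nIter = 30) {
  n <- convGridShape(imageSide, dict@filterSide, dict@stride)[1]
  a <- matrix(1, n * n, ncol(dict@filters))
  lam <- 1
  for (i in seq_len(nIter)) {
    img <- overlapAdd(a, dict, imageSide)
    a2 <- extractPatches(img, dict@filterSide, dict@stride) %*% dict@filters
    lam <- sqrt(sum(a2^2)) / sqrt(sum(a^2))
    a <- a2 / sqrt(sum(a2^2))
  }
  lam
}

#' Learn a sparse-coding dictionary from image patches
#'
#' Alternates L1-penalized sparse inference (ISTA) on a batch of patches
#' with a least-squares dictionary update, renormalizing every filter to
#' unit Euclidean norm after each update. The reconstruction objective
#' `0.5 * ||X - D A||^2 + sparsity * ||A||_1` is recorded per outer
#' iteration and is non-increasing up to the renormalization step.
#'
#' @param patches numeric matrix with one vectorized square patch per
#'   column (`filterSide^2` rows), or a list of square matrices.
#' @param nFilters number of dictionary filters to learn.
#' @param sparsity L1 penalty weight (default 0.5).
#' @param nIter outer alternation iterations (default 30).
#' @param seed integer RNG seed (filter initialization, patch order).
#' @param stride stride stored with the dictionary for later encoding.
#' @param center subtract each patch's mean first (default TRUE).
#' @return a [SparseDictionary-class].
#' @export
learnDictionary <- function(patches, nFilters = 64L, sparsity = 0.5,
                            nIter = 30L, seed = 1L, stride = 3L,
                            center = TRUE) {
  if (is.list(patches))
    patches <- vapply(patches, as.vector, numeric(length(patches[[1]])))
  if (any(!is.finite(patches))) stop("non-finite patches")
  if (nIter <= 0) stop("nIter must be positive")
  if (ncol(patches) < nFilters)
    stop("need at least as many patches as filters")
  f <- as.integer(round(sqrt(nrow(patches))))
  if (f^2 != nrow(patches)) stop("patches must be square")
  if (center) patches <- sweep(patches, 2, colMeans(patches))

  obj <- numeric(nIter)
  D <- withSeed(seed, {
    init <- patches[, sample.int(ncol(patches), nFilters), drop = FALSE]
    init <- init + matrix(rnorm(length(init), sd = 1e-3), nrow(init))
    sweep(init, 2, pmax(sqrt(colSums(init^2)), 1e-12), "/")
  })
  X <- patches
  for (it in seq_len(nIter)) {
    A <- istaBatch(X, D, sparsity, nSteps = 50L)
    obj[it] <- 0.5 * sum((X - D %*% A)^2) + sparsity * sum(abs(A))
    G <- A %*% t(A) + 1e-8 * diag(nFilters)
    D <- t(solve(G, A %*% t(X)))
    dead <- sqrt(colSums(D^2)) < 1e-10
    if (any(dead)) { # re-seed dead filters from worst-reconstructed patches
      err <- colSums((X - D %*% A)^2)
      D[, dead] <- X[, order(err, decreasing = TRUE)[seq_len(sum(dead))]]
    }
    D <- sweep(D, 2, pmax(sqrt(colSums(D^2)), 1e-12), "/")
  }
  new("SparseDictionary", filters = D, filterSide = f,
      stride = as.integer(stride), seed = as.integer(seed),
      objective = obj)
}

# ISTA for the non-convolutional patch model X ~ D A (columns independent)
istaBatch <- function(X, D, lambda, nSteps = 50L) {
  L <- max(eigen(crossprod(D), symmetric = TRUE, only.values = TRUE)$values)
  L <- max(L, 1e-8)
  A <- matrix(0, ncol(D), ncol(X))
  DtX <- crossprod(D, X)
  DtD <- crossprod(D)
  for (i in seq_len(nSteps))
    A <- softThreshold(A + (DtX - DtD %*% A) / L, lambda / L)
  A
}

#' Encode an image into its convolutional sparse code
#'
#' Runs ISTA on the convolutional generative model (valid placements at
#' the dictionary stride, overlap-add reconstruction) to infer the
#' coefficient field, then multiplies by `scale`. The result is the
#' feedforward drive of the circuit: an `nRows x nCols x nFilters` array
#' over hypercolumn positions and feature channels.
#'
#' @param image square grayscale matrix with values in \[0,1\] (values
#'   outside are clamped with a warning).
#' @param dict a [SparseDictionary-class].
#' @param scale multiplier applied to the inferred coefficients
#'   (default 30, the training drive scaling).
#' @param sparsity L1 penalty weight (default 0.5).
#' @param nSteps ISTA iterations (default 120).
#' @return 3-d coefficient array with attributes `scale` and `objective`.
#' @export
encodeImage <- function(image, dict, scale = 30, sparsity = 0.5,
                        nSteps = 120L) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix")
  if (min(image) < 0 || max(image) > 1) {
    warning("image values outside [0,1]; clamping")
    image <- pmin(pmax(image, 0), 1)
  }
  f <- dict@filterSide
  grid <- convGridShape(nrow(image), f, dict@stride)
  nd <- ncol(dict@filters)
  L <- max(convLipschitz(dict, nrow(image)), 1e-8)
  A <- matrix(0, grid[1] * grid[2], nd)
  for (i in seq_len(nSteps)) {
    resid <- image - overlapAdd(A, dict, nrow(image))
    grad <- -extractPatches(resid, f, dict@stride) %*% dict@filters
    A <- softThreshold(A - grad / L, sparsity / L)
  }
  resid <- image - overlapAdd(A, dict, nrow(image))
  code <- array(0, dim = c(grid[1], grid[2], nd))
  for (d in seq_len(nd))
    code[, , d] <- matrix(A[, d], grid[1], grid[2], byrow = TRUE)
  code <- code * scale
  attr(code, "scale") <- scale
  attr(code, "objective") <- 0.5 * sum(resid^2) + sparsity * sum(abs(A))
  attr(code, "residual") <- sqrt(sum(resid^2))
  code
}

#' Reconstruct an image from a sparse code
#'
#' Inverse of the generative model used by [encodeImage()]: divides out
#' the drive scale and overlap-adds the dictionary filters at every
#' placement.
#'
#' @param code coefficient array from [encodeImage()].
#' @param dict the [SparseDictionary-class] used to encode.
#' @param imageSide side length of the reconstruction canvas.
#' @return reconstructed image matrix.
#' @export
decodeCode <- function(code, dict, imageSide) {
  sc <- attr(code, "scale")
  if (is.null(sc)) sc <- 1
  grid <- dim(code)[1:2]
  A <- matrix(0, grid[1] * grid[2], dim(code)[3])
  for (d in seq_len(dim(code)[3]))
    A[, d] <- as.vector(t(code[, , d]))
  overlapAdd(A / sc, dict, imageSide)
}

#' Flatten a sparse-code array to the circuit's neuron ordering
#'
#' Maps the `(row, column, channel)` coefficient field onto the flat
#' excitatory neuron index used by [buildConnectivity()] (channel
#' fastest, then grid column, then grid row).
#'
#' @param code 3-d array from [encodeImage()].
#' @return numeric vector of length `nRows * nCols * nChannels`.
#' @export
flattenCode <- function(code) {
  d <- dim(code)
  out <- numeric(prod(d))
  for (r in seq_len(d[1])) for (cc in seq_len(d[2]))
    out[((r - 1) * d[2] + (cc - 1)) * d[3] + seq_len(d[3])] <- code[r, cc, ]
  out
}
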