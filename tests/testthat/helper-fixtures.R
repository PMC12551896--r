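# Shared fixtures, all built in code.

# tiny circuit: 2 x 2 grid, 4 channels -> 16 E + 16 I neurons
tinyConfig <- function(...) {
  networkConfig(nRows = 2L, nCols = 2L, nChannels = 4L, radiusE = 1L,
                radiusI = 1L, ...)
}

# handcrafted nonnegative unit-norm dictionary with disjoint supports
blockDictionary <- function(filterSide = 3L, nFilters = 3L, stride = 3L) {
  f2 <- filterSide^2
  filters <- matrix(0, f2, nFilters)
  for (j in seq_len(nFilters)) {
    idx <- ((j - 1L) * 3L) %% f2 + 1:3
    filters[idx, j] <- c(0.5, 1, 0.5)
  }
  filters <- sweep(filters, 2, sqrt(colSums(filters^2)), "/")
  new("SparseDictionary", filters = filters,
      filterSide = as.integer(filterSide), stride = as.integer(stride),
      seed = 0L, objective = numeric(0))
}

# random diagonalizable linearization of size n (spectral radius kept < 1)
randomLinearization <- function(n, nExc = n, seed = 1) {
  set.seed(seed)
  W <- matrix(rnorm(n * n, sd = 0.5 / sqrt(n)), n, n)
  sp <- runif(n, 0.1, 2)
  A <- diag(n) - sp * W
  M <- solve(A)
  new("Linearization", sigmaPrime = sp, M = M,
      J = sweep(M, 2, sp, "*"), rStar = runif(n),
      nExc = as.integer(nExc), attractorId = paste0("rand", seed))
}

# toy fixed-point table: explicit vectors per (target, level, sample)
toyFixedPointTable <- function(vectors, targets, levels, samples) {
  records <- lapply(seq_along(targets), function(i) {
    id <- if (levels[i] == 0) targets[i]
          else sprintf("%s_n%02d_k%02d", targets[i],
                       round(100 * levels[i]), samples[i])
    new("FixedPointRecord", stimulusId = id, noiseLevel = levels[i],
        sampleIndex = as.integer(samples[i]), rStar = vectors[[i]],
        riStar = numeric(length(vectors[[i]])), residual = 0,
        converged = TRUE, steps = 1L,
        popTrace = 0, rMean = vectors[[i]])
  })
  fixedPointTable(records)
}

# brute-force distance oracle: direct double loops over the table
bruteDistances <- function(vectors, targets, levels, samples) {
  en <- function(i, j) sqrt(sum((vectors[[i]] - vectors[[j]])^2))
  u <- sort(unique(levels))
  out <- NULL
  for (i in seq_along(vectors)) {
    if (levels[i] == 0) next
    nl <- u[match(levels[i], u) - 1]
    jLev <- which(targets == targets[i] & levels == nl)
    jRes <- which(targets == targets[i] & levels == levels[i] &
                    seq_along(vectors) != i)
    jSig <- which(targets != targets[i] & levels == levels[i])
    out <- rbind(out, data.frame(
      targetId = targets[i], level = levels[i], sample = samples[i],
      Dlev = mean(vapply(jLev, en, numeric(1), i = i)),
      Dres = if (length(jRes)) mean(vapply(jRes, en, numeric(1), i = i))
             else NA_real_,
      Dsig = if (length(jSig)) mean(vapply(jSig, en, numeric(1), i = i))
             else NA_real_))
  }
  out
}

# memoized scaled-down protocol runs shared by the heavier tests
.runCache <- new.env(parent = emptyenv())

scaledFamiliarityRun <- function() {
  if (is.null(.runCache$fam)) {
    cfg <- experimentConfig("familiarity", "scaled", seed = 101L)
    .runCache$fam <- runFamiliarity(cfg)
  }
  .runCache$fam
}

scaledAssociationRun <- function() {
  if (is.null(.runCache$assoc)) {
    cfg <- experimentConfig("association", "scaled", seed = 202L)
    .runCache$assoc <- runAssociation(cfg)
  }
  .runCache$assoc
}
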