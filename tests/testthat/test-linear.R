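test_that("linearization has the closed forms at simple attractors", {
  # attractor at zero with zero drive: sigma' = 0, J = 0, M = I
  cfg <- tinyConfig()
  conn <- buildConnectivity(cfg)
  fp <- runToFixedPoint(conn, numeric(16))
  lin <- linearize(conn, fp, numeric(16))
  expect_equal(lin@sigmaPrime, numeric(32))
  expect_equal(lin@J, matrix(0, 32, 32))
  expect_equal(lin@M, diag(32))
  # invariants: J = M S' and (I - S'W)M = I
  set.seed(30)
  alpha <- rexp(16)
  fp2 <- runToFixedPoint(conn, alpha)
  lin2 <- linearize(conn, fp2, alpha)
  W <- rbind(cbind(conn@Wee, conn@Wei), cbind(conn@Wie, matrix(0, 16, 16)))
  expect_equal(lin2@J, sweep(lin2@M, 2, lin2@sigmaPrime, "*"),
               tolerance = 1e-12)
  expect_equal((diag(32) - lin2@sigmaPrime * W) %*% lin2@M, diag(32),
               tolerance = 1e-8)
})

test_that("the Jacobian predicts fixed-point shifts to second order", {
  # 2-neuron toy: finite-difference check on the excitatory block
  cfg <- networkConfig(1L, 2L, 1L, radiusE = 1L, radiusI = 1L,
                       wEE = 0.3, wIE = 0.5)
  conn <- buildConnectivity(cfg)
  alpha <- c(0.5, 0.3)
  fp <- runToFixedPoint(conn, alpha, tol = 1e-12)
  lin <- linearize(conn, fp, alpha)
  dalpha <- c(0.3, -0.2)
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3), function(eps) {
    fpP <- runToFixedPoint(conn, alpha + eps * dalpha, tol = 1e-12)
    pred <- steadyState(fp) +
      eps * as.numeric(lin@J[1:2, 1:2] %*% dalpha)
    max(abs(steadyState(fpP) - pred))
  }, numeric(1))
  # halving eps quarters the error (O(eps^2))
  expect_lt(errs[2] / errs[1], 0.35)
  expect_lt(errs[3] / errs[2], 0.35)
})

test_that("gain modes reconstruct the gain matrix and satisfy biorthogonality", {
  lin <- randomLinearization(15, seed = 31)
  gm <- gainModes(lin)
  expect_false(gm@defective)
  Mrec <- gm@Wright %*% (gm@mu * t(gm@Vleft))
  expect_lt(max(Mod(Mrec - lin@M)), 1e-8)
  B <- t(gm@Vleft) %*% gm@Wright
  expect_lt(max(Mod(B - diag(15))), 1e-8)
  # symmetric gain matrix: real spectrum, orthonormal eigenvectors
  S <- (lin@M + t(lin@M)) / 2
  linS <- new("Linearization", sigmaPrime = lin@sigmaPrime, M = S,
              J = sweep(S, 2, lin@sigmaPrime, "*"), rStar = lin@rStar,
              nExc = 15L, attractorId = "sym")
  gmS <- gainModes(linS)
  expect_lt(max(abs(Im(gmS@mu))), 1e-10)
  expect_lt(max(Mod(t(Conj(gmS@Wright)) %*% gmS@Wright - diag(15))), 1e-8)
  # scalar gain matrix: all eigenvalues equal
  linC <- new("Linearization", sigmaPrime = rep(1, 4), M = diag(4) * 2.5,
              J = diag(4) * 2.5, rStar = numeric(4), nExc = 4L,
              attractorId = "c")
  expect_equal(Re(gainModes(linC)@mu), rep(2.5, 4))
})

test_that("collective modes decompose the squared Jacobian distance exactly", {
  for (seed in 32:34) {
    lin <- randomLinearization(20, nExc = 12L, seed = seed)
    gm <- gainModes(lin)
    cms <- collectiveModes(gm)
    expect_true(all(modeSpectrum(cms) >= -1e-10))
    expect_true(all(diff(modeSpectrum(cms)) <= 1e-12))
    set.seed(seed + 100)
    deltas <- matrix(rnorm(20 * 5), 20, 5)
    deltas <- sweep(deltas, 2, sqrt(colSums(deltas^2)), "/")
    # oracle: direct Jacobian products
    lhs <- mean(colSums((lin@J %*% deltas)^2))
    rhs <- linearizedDistance(cms, deltas, K = 20L)
    expect_equal(rhs, lhs, tolerance = 1e-6)
    # excitatory projection variant
    cmsE <- collectiveModes(gm, outputIdx = 1:12)
    lhsE <- mean(colSums((lin@J[1:12, ] %*% deltas)^2))
    expect_equal(linearizedDistance(cmsE, deltas, K = 20L), lhsE,
                 tolerance = 1e-6)
    # rank-1 gain matrix: the mode decomposition spans a rank-1 distance
    # operator (sum_k lambda_k phi_k phi_k^H = J^T J of rank 1)
    u <- rnorm(8); v <- rnorm(8)
    lin1 <- new("Linearization", sigmaPrime = rep(1, 8),
                M = u %o% v, J = u %o% v, rStar = numeric(8),
                nExc = 8L, attractorId = "r1")
    cms1 <- collectiveModes(gainModes(lin1))
    B <- cms1@Phi %*% (modeSpectrum(cms1) * Conj(t(cms1@Phi)))
    expect_lt(max(Mod(B - t(lin1@J) %*% lin1@J)), 1e-8)
    sv <- svd(Re(B))$d
    expect_equal(sum(sv > 1e-8 * sv[1]), 1)
  }
})

test_that("input deltas are unit, class-correct and enumerated like the distances", {
  # codes for T=2, L=1, K=2 plus cleans: 6 stimuli
  info <- data.frame(
    targetId = c("A", "A", "A", "B", "B", "B"),
    level = c(0, 0.1, 0.1, 0, 0.1, 0.1),
    sample = c(0L, 1L, 2L, 0L, 1L, 2L))
  set.seed(35)
  codes <- matrix(rexp(24), 4, 6)
  sig <- inputDeltas(codes, info, "signal")
  lev <- inputDeltas(codes, info, "level")
  res <- inputDeltas(codes, info, "residual")
  # brute-force pair counts: signal 2x2 unordered cross-target pairs = 4;
  # level = one per noisy sample = 4; residual = 1 unordered pair per target
  expect_equal(ncol(sig), 4)
  expect_equal(ncol(lev), 4)
  expect_equal(ncol(res), 2)
  expect_equal(colSums(sig^2), rep(1, 4), tolerance = 1e-12)
  expect_equal(colSums(res^2), rep(1, 2), tolerance = 1e-12)
  # identical codes are dropped
  codes2 <- codes; codes2[, 5] <- codes2[, 2]; codes2[, 6] <- codes2[, 2]
  info2 <- info; info2$targetId <- "A"  # single target, residual class
  expect_error(inputDeltas(codes2[, c(1, 2, 5, 6)],
                           data.frame(targetId = "A",
                                      level = c(0, 0.1, 0.1, 0.1),
                                      sample = c(0L, 1L, 2L, 3L)),
                           "residual"),
               "zero difference")
})

test_that("alignments match brute force and orientation labels threshold correctly", {
  lin <- randomLinearization(10, seed = 36)
  cms <- collectiveModes(gainModes(lin))
  set.seed(37)
  deltas <- matrix(rnorm(30), 10, 3)
  deltas <- sweep(deltas, 2, sqrt(colSums(deltas^2)), "/")
  g <- modeAlignment(cms, deltas)
  # brute force: mean |phi^H d|^2 per mode
  gBrute <- vapply(seq_len(10), function(k)
    mean(abs(t(Conj(cms@Phi[, k])) %*% deltas)^2), numeric(1))
  expect_equal(g, gBrute, tolerance = 1e-10)
  expect_true(all(g >= 0))
  # C = I gives ||phi||^2
  gI <- modeAlignment(cms, diag(10), isDeltas = FALSE)
  expect_equal(gI, Re(colSums(Conj(cms@Phi) * cms@Phi)), tolerance = 1e-10)
  # orientation labels
  expect_equal(classifyOrientation(c(1, 0, 0.5), c(0, 1, 0.49)),
               c("signal", "noise", "neutral"))
  expect_equal(classifyOrientation(c(1, 1), c(1, 1)), rep("neutral", 2))
})

test_that("sensitivities satisfy the weighted-sum identities and match finite differences", {
  lam <- c(2, 1.5, 1, 0.5, 0.1)
  g <- c(0.3, 0.8, 0.2, 0.5, 0.9)
  s <- modeSensitivities(lam, g)
  expect_equal(sum(lam * s$dLambda), 1, tolerance = 1e-12)
  expect_equal(sum(g * s$dG), 1, tolerance = 1e-12)
  # two modes, lambda = g = 1: each spectrum sensitivity is 1/2
  s2 <- modeSensitivities(c(1, 1), c(1, 1))
  expect_equal(s2$dLambda, c(0.5, 0.5))
  # finite-difference oracle on Dtilde = dD / D_pre
  D0 <- sum(lam * g)
  eps <- 1e-4
  for (k in 1:5) {
    lamP <- lam; lamP[k] <- lamP[k] + eps
    expect_equal((sum(lamP * g) - D0) / D0, s$dLambda[k] * eps,
                 tolerance = 1e-8)
    gP <- g; gP[k] <- gP[k] + eps
    expect_equal((sum(lam * gP) - D0) / D0, s$dG[k] * eps,
                 tolerance = 1e-8)
  }
  expect_true(all(is.na(modeSensitivities(c(1, 1), c(0, 0))$dG)))
})

test_that("mode change statistics track constructed spectrum and alignment changes", {
  # construct modes analytically in a 4-d input space
  basis <- diag(4) + 0i
  pre <- new("CollectiveModeSet", lambda = c(2, 1), Q = basis[, 1:2],
             Phi = basis[, 1:2], attractorId = "x")
  # post: mode 1 doubled spectrum, same filter; mode 2 rotated toward the
  # signal direction e3
  rot <- (basis[, 2] + basis[, 3]) / sqrt(2)
  post <- new("CollectiveModeSet", lambda = c(4, 1),
              Q = cbind(basis[, 1], rot), Phi = cbind(basis[, 1], rot),
              attractorId = "x")
  sigDelta <- matrix(c(0, 0, 1, 0), 4, 1)   # signal direction e3
  noiseDelta <- matrix(c(0, 1, 0, 0), 4, 1) # noise direction e2
  aPre <- list(signal = modeAlignment(pre, sigDelta),
               level = modeAlignment(pre, noiseDelta),
               residual = modeAlignment(pre, noiseDelta))
  aPost <- list(signal = modeAlignment(post, sigDelta),
                level = modeAlignment(post, noiseDelta),
                residual = modeAlignment(post, noiseDelta))
  st <- modeChangeStats(pre, post, aPre, aPost, K = 2L)
  expect_equal(st$matched, 1:2)
  expect_equal(st$dLambda, c(2, 0))
  expect_equal(st$dLambdaNorm, c(1, 0))
  expect_true(st$dgSignal[2] > 0)   # rotated mode gains signal alignment
  expect_true(st$dgNoise[2] < 0)    # and loses noise alignment
  expect_true(st$includedLambda[1] && !st$includedLambda[2])
  # identical pre/post: all changes zero
  st0 <- modeChangeStats(pre, pre, aPre, aPre, K = 2L)
  expect_true(all(st0$dLambda == 0) && all(st0$dgSignal == 0))
})

test_that("the first-order compression condition matches exact ratio changes", {
  # equal fractional changes -> deltaR = 0
  cc <- compressionCondition(2, 1, 2.2, 1.1)
  expect_equal(cc$deltaR, 0, tolerance = 1e-12)
  expect_false(cc$compresses)
  # stronger signal growth -> compression
  cc2 <- compressionCondition(2, 1, 2.4, 1.1)  # Dtilde sig .2 > noise .1
  expect_lt(cc2$deltaR, 0)
  expect_true(cc2$compresses)
  # numeric toy: first-order deltaR approximates the exact ratio change
  Ds <- 3; Dn <- 1.2
  errs <- vapply(c(1e-2, 5e-3), function(eps) {
    cc3 <- compressionCondition(Ds, Dn, Ds * (1 + 2 * eps), Dn * (1 + eps))
    exact <- Dn * (1 + eps) / (Ds * (1 + 2 * eps)) - Dn / Ds
    abs(cc3$deltaR - exact)
  }, numeric(1))
  expect_lt(errs[2] / errs[1], 0.35)  # first-order: error shrinks as eps^2
})
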