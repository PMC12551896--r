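test_that("index map is a bijection over the whole grid", {
  cfg <- tinyConfig()
  ks <- integer(0)
  for (r in 1:2) for (cc in 1:2) for (d in 1:4) {
    k <- flattenIndex(r, cc, d, cfg)
    expect_equal(unflattenIndex(k, cfg), c(r, cc, d))
    ks <- c(ks, k)
  }
  expect_setequal(ks, 1:16)
})

test_that("neighborhood sizes match the interior formulas and clip at borders", {
  # 5x5 grid x 64 channels: interior neuron sees the printed values
  cfg <- networkConfig(5L, 5L, 64L, radiusE = 2L, radiusI = 1L)
  conn <- buildConnectivity(cfg)
  sizes <- neighborhoodSizes(conn)
  center <- flattenIndex(3L, 3L, 1L, cfg)
  expect_equal(sizes$NE[center], 64L * 25L)      # Nd * (2Re+1)^2 = 1600
  expect_equal(sizes$NI[center], 9L + 63L)       # (2Ri+1)^2 + Nd - 1 = 72
  # corner hypercolumn: clipped 3x3 square of hypercolumns
  corner <- flattenIndex(1L, 1L, 1L, cfg)
  expect_equal(sizes$NE[corner], 64L * 9L)       # enumerated: 576
  expect_equal(sizes$NI[corner], 4L + 63L)       # clipped 2x2 same-channel
})

test_that("connectivity initialization satisfies its invariants", {
  cfg <- tinyConfig(wEE = 5, wIE = 20)
  conn <- buildConnectivity(cfg)
  expect_equal(unname(rowSums(eeWeights(conn))), rep(5, 16), tolerance = 1e-12)
  expect_true(all(eeWeights(conn)[eeMask(conn) == 0] == 0))
  expect_true(all(eiWeights(conn) == -1 / 16))
  wie <- ieWeights(conn)
  expect_equal(unname(rowSums(wie)), rep(20, 16), tolerance = 1e-12)
  # uniform on support
  for (k in 1:16) {
    nz <- wie[k, wie[k, ] > 0]
    expect_equal(unname(nz), rep(nz[1], length(nz)))
  }
  # translation symmetry: interior weights depend only on offset/channel;
  # on a 3x3 grid with radiusE=1 the two neurons of the same channel at
  # different interior-equivalent positions have identical row profiles
  cfg3 <- networkConfig(3L, 3L, 2L, radiusE = 1L, radiusI = 1L, wIE = 20)
  conn3 <- buildConnectivity(cfg3)
  expect_error(buildConnectivity(networkConfig(nChannels = 0L)),
               "nChannels")
})

test_that("activation is the squared rectifier", {
  expect_equal(activation(-1), 0)
  expect_equal(activation(3), 9)
  expect_equal(activation(0), 0)
  expect_equal(activationDeriv(c(-2, 0, 3)), c(0, 0, 6))
})

test_that("zero input leaves the zero state exactly fixed", {
  cfg <- tinyConfig()
  conn <- buildConnectivity(cfg)
  st <- list(re = numeric(16), ri = numeric(16))
  st2 <- stepNetwork(st, conn, numeric(16))
  expect_identical(st2$re, numeric(16))
  expect_identical(st2$ri, numeric(16))
  fp <- runToFixedPoint(conn, numeric(16))
  expect_true(fp@converged)
  expect_identical(steadyState(fp), numeric(16))
})

test_that("an isolated neuron converges to the square of its drive", {
  cfg <- networkConfig(1L, 1L, 1L, radiusE = 0L, radiusI = 0L,
                       wEE = 0, wIE = 0)
  conn <- buildConnectivity(cfg)
  conn@Wee[] <- 0; conn@Wei[] <- 0; conn@Wie[] <- 0
  a <- 0.7
  fp <- runToFixedPoint(conn, a)
  expect_true(fp@converged)
  expect_equal(steadyState(fp), a^2, tolerance = 1e-4)
})

test_that("fixed points match an independent Newton solve in the smooth regime", {
  # 2-neuron excitatory chain, small weights, no inhibition
  cfg <- networkConfig(1L, 2L, 1L, radiusE = 1L, radiusI = 0L,
                       wEE = 0.2, wIE = 0)
  conn <- buildConnectivity(cfg)
  conn@Wie[] <- 0; conn@Wei[] <- 0
  alpha <- c(0.6, 0.4)
  # oracle: damped Newton on G(r) = r - (W r + a)^2 with analytic Jacobian
  W <- eeWeights(conn)
  r <- c(0.5, 0.5)
  for (i in 1:200) {
    z <- as.numeric(W %*% r + alpha)
    G <- r - pmax(z, 0)^2
    Jg <- diag(2) - (2 * pmax(z, 0)) * W
    r <- r - 0.5 * solve(Jg, G)
  }
  expect_lt(max(abs(r - pmax(as.numeric(W %*% r + alpha), 0)^2)), 1e-12)
  fp <- runToFixedPoint(conn, alpha, tol = 1e-10)
  expect_true(fp@converged)
  expect_equal(steadyState(fp), r, tolerance = 1e-6)
})

test_that("converged records satisfy the fixed-point residual bound", {
  cfg <- tinyConfig(wIE = 20)
  conn <- buildConnectivity(cfg)
  set.seed(11)
  alpha <- rexp(16)
  tol <- 1e-6
  fp <- runToFixedPoint(conn, alpha, maxT = 3000, tol = tol)
  expect_true(fp@converged)
  re <- steadyState(fp); ri <- fp@riStar
  resid <- max(abs(re - activation(as.numeric(
    eeWeights(conn) %*% re + eiWeights(conn) %*% ri + alpha))))
  expect_lt(resid, 10 * tol)
  # deterministic dynamics: identical reruns
  fp2 <- runToFixedPoint(conn, alpha, maxT = 3000, tol = tol)
  expect_identical(steadyState(fp2), steadyState(fp))
})

test_that("compiled integrator agrees with the reference R step", {
  cfg <- tinyConfig(wIE = 20)
  conn <- buildConnectivity(cfg)
  set.seed(2)
  alpha <- rexp(16)
  st <- list(re = numeric(16), ri = numeric(16))
  for (i in 1:50) st <- stepNetwork(st, conn, alpha)
  res <- famcirc:::cpp_presentation(conn@Wee, conn@Wei, conn@Wie, conn@mask,
                                    alpha, numeric(16), 0L, 50L,
                                    cfg@tauE, cfg@tauI, cfg@dt,
                                    2e9, 2e7, cfg@divergenceBound)
  expect_equal(as.numeric(res$re), st$re, tolerance = 1e-12)
  expect_equal(as.numeric(res$ri), st$ri, tolerance = 1e-12)
})

test_that("divergent dynamics raise an instability error naming the population", {
  cfg <- networkConfig(1L, 2L, 1L, radiusE = 1L, radiusI = 0L,
                       wEE = 10, wIE = 0, divergenceBound = 1e6)
  conn <- buildConnectivity(cfg)
  conn@Wie[] <- 0; conn@Wei[] <- 0
  expect_error(runToFixedPoint(conn, c(50, 50)), "excitatory")
})
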