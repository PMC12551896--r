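# hand-listed toy representation: 2 targets x 2 levels x 2 samples + cleans
toyCase <- function(seed = 20) {
  set.seed(seed)
  targets <- c("A", rep("A", 4), "B", rep("B", 4))
  levels <- c(0, 0.1, 0.1, 0.3, 0.3, 0, 0.1, 0.1, 0.3, 0.3)
  samples <- c(0L, 1L, 2L, 1L, 2L, 0L, 1L, 2L, 1L, 2L)
  vectors <- lapply(seq_along(levels), function(i) rexp(6))
  list(vectors = vectors, targets = targets, levels = levels,
       samples = samples,
       fpt = toyFixedPointTable(vectors, targets, levels, samples))
}

test_that("distance table matches the brute-force oracle on a toy table", {
  tc <- toyCase()
  tab <- distanceTable(tc$fpt)
  oracle <- bruteDistances(tc$vectors, tc$targets, tc$levels, tc$samples)
  tab <- tab[order(tab$targetId, tab$level, tab$sample), ]
  oracle <- oracle[order(oracle$targetId, oracle$level, oracle$sample), ]
  expect_equal(tab$Dlev, oracle$Dlev, tolerance = 1e-12)
  expect_equal(tab$Dres, oracle$Dres, tolerance = 1e-12)
  expect_equal(tab$Dsig, oracle$Dsig, tolerance = 1e-12)
  expect_equal(tab$Rlev, oracle$Dlev / oracle$Dsig, tolerance = 1e-12)
  # scalar accessors agree with the table
  expect_equal(levelDistance(tc$fpt, 0.3, "A", 1),
               tab$Dlev[tab$targetId == "A" & tab$level == 0.3 &
                          tab$sample == 1])
  expect_equal(residualDistance(tc$fpt, 0.1, "B", 2),
               tab$Dres[tab$targetId == "B" & tab$level == 0.1 &
                          tab$sample == 2])
})

test_that("degenerate geometries give the closed-form distances", {
  # all representations identical -> all distances zero
  v <- lapply(1:10, function(i) rep(1, 4))
  tc <- toyCase()
  fpt <- toyFixedPointTable(v, tc$targets, tc$levels, tc$samples)
  expect_warning(tab <- distanceTable(fpt), "zero signal distance")
  expect_true(all(tab$Dlev == 0) && all(tab$Dres == 0) && all(tab$Dsig == 0))
  expect_true(all(is.na(tab$Rlev)))
  # 1-D ladder: representation = level index for every sample -> Dlev = 1
  lv <- c(0, 1, 1, 2, 2)
  fpt2 <- toyFixedPointTable(lapply(lv, function(x) x),
                             rep("A", 5), lv / 10, c(0L, 1L, 2L, 1L, 2L))
  expect_error(distanceTable(fpt2), NA)
  tab2 <- suppressMessages(distanceTable(fpt2))
  expect_true(all(tab2$Dlev == 1))
  expect_true(all(tab2$Dres == 0))
  expect_true(all(is.na(tab2$Dsig)))  # single target
  # two targets at distance d, clean plus one level at the target itself
  fpt3 <- toyFixedPointTable(list(c(0, 0), c(0, 0), c(3, 4), c(3, 4)),
                             c("A", "A", "B", "B"), c(0, 0.1, 0, 0.1),
                             c(0L, 1L, 0L, 1L))
  tab3 <- distanceTable(fpt3)
  expect_equal(tab3$Dsig, c(5, 5))
})

test_that("relative distances are invariant under isometry and scale", {
  tc <- toyCase(21)
  tab <- distanceTable(tc$fpt)
  set.seed(22)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  vecs2 <- lapply(tc$vectors, function(v) 2.7 * as.numeric(Q %*% v))
  tab2 <- distanceTable(toyFixedPointTable(vecs2, tc$targets, tc$levels,
                                           tc$samples))
  expect_equal(tab2$Rlev, tab$Rlev, tolerance = 1e-10)
  expect_equal(tab2$Rres, tab$Rres, tolerance = 1e-10)
  expect_equal(tab2$Dsig, 2.7 * tab$Dsig, tolerance = 1e-10)
})

test_that("manifold objective has its closed-form endpoints and brute-force value", {
  # all-equal within target, distinct across -> objective 0
  v <- list(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  fpt <- toyFixedPointTable(v, c("A", "A", "B", "B"), c(0, 0.1, 0, 0.1),
                            c(0L, 1L, 0L, 1L))
  expect_equal(manifoldObjective(fpt), 0)
  # brute-force oracle on a random toy
  tc <- toyCase(23)
  D2 <- as.matrix(dist(t(vapply(tc$vectors, identity, numeric(6)))))^2
  total <- 0
  for (i in seq_along(tc$vectors)) {
    nb <- which(tc$targets == tc$targets[i] & seq_along(tc$vectors) != i)
    ot <- which(tc$targets != tc$targets[i])
    total <- total + mean(D2[i, nb]) / mean(D2[i, ot])
  }
  expect_equal(manifoldObjective(tc$fpt), total, tolerance = 1e-12)
})

test_that("compression correlation matches the textbook formula", {
  # perfectly linear series
  x <- c(1, 2, 3, 4, 5); y <- 2 - 0.5 * x
  cc <- compressionCorrelation(x, y)
  expect_equal(cc$r, -1)
  expect_equal(cc$slope, -0.5)
  expect_equal(cc$intercept, 2)
  # constant series -> undefined
  expect_true(is.na(compressionCorrelation(x, rep(1, 5))$r))
  expect_true(is.na(compressionCorrelation(x[1:2], y[1:2])$r))
  # hand-listed 5-point series against the direct formula
  x2 <- c(0.2, 0.5, 0.1, 0.9, 0.4); y2 <- c(1.1, 0.3, 0.8, 0.2, 0.9)
  cc2 <- compressionCorrelation(x2, y2)
  rHand <- sum((x2 - mean(x2)) * (y2 - mean(y2))) /
    sqrt(sum((x2 - mean(x2))^2) * sum((y2 - mean(y2))^2))
  expect_equal(cc2$r, rHand, tolerance = 1e-12)
  bHand <- sum((x2 - mean(x2)) * (y2 - mean(y2))) / sum((x2 - mean(x2))^2)
  expect_equal(cc2$slope, bHand, tolerance = 1e-12)
})

test_that("non-converged stimuli are excluded from the table with a message", {
  tc <- toyCase(24)
  records <- lapply(seq_along(tc$vectors), function(i) {
    id <- if (tc$levels[i] == 0) tc$targets[i]
          else sprintf("%s_n%02d_k%02d", tc$targets[i],
                       round(100 * tc$levels[i]), tc$samples[i])
    new("FixedPointRecord", stimulusId = id, noiseLevel = tc$levels[i],
        sampleIndex = tc$samples[i], rStar = tc$vectors[[i]],
        riStar = numeric(6), residual = 0, converged = i != 3L,
        steps = 1L, popTrace = 0, rMean = tc$vectors[[i]])
  })
  fpt <- fixedPointTable(records)
  expect_message(tab <- distanceTable(fpt), "non-converged")
  expect_equal(nrow(tab), 7)  # 8 noisy stimuli minus the dropped one
})
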