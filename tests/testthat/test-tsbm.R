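test_that("block probabilities follow the planted-partition form", {
  pr <- tsbmParams("community_label", n = 200, k = 5, p = 0.8, mu = 0.2,
                   c = 10, thetaHet = FALSE)
  lab <- rep(1:5, each = 40)
  P <- blockProbability(pr, lab)
  expect_equal(P[1, 2], 0.21)            # within  = (c/n)((1-mu)k + mu)
  expect_equal(P[1, 41], 0.01)           # between = (c/n)mu
  expect_true(isSymmetric(P))
  expect_true(all(diag(P) == 0))

  # k = 1: structureless degree-corrected random graph
  pr1 <- tsbmParams("community_label", n = 100, k = 1, mu = 0.3, c = 8,
                    thetaHet = FALSE)
  expect_true(all(abs(blockProbability(pr1, rep(1L, 100), 1:50, 51:100) -
                        8 / 100) < 1e-12))
  # mu = 1: within equals between
  prU <- tsbmParams("community_label", n = 100, k = 4, mu = 1, c = 8,
                    thetaHet = FALSE)
  labU <- rep(1:4, each = 25)
  PU <- blockProbability(prU, labU)
  expect_equal(PU[1, 2], PU[1, 99])

  # empirical edge frequencies match the probabilities
  prE <- tsbmParams("edge_correlated", n = 80, layers = 60, k = 2, p = 0,
                    mu = 0.2, c = 10, thetaHet = FALSE)
  real <- generateTSBM(prE, seed = 5)
  d <- allDyads(80)
  cnt <- numeric(nrow(d))
  for (t in 1:60)
    cnt[seqstack:::edgeDyadIndices(getLayer(real@net, t), 80)] <-
      cnt[seqstack:::edgeDyadIndices(getLayer(real@net, t), 80)] + 1
  Pvec <- seqstack:::blockProbabilityVec(real@params, real@labels[1, ])
  same <- real@labels[1, d[, 1]] == real@labels[1, d[, 2]]
  expect_equal(mean(cnt[same] / 60), mean(Pvec[same]), tolerance = 0.05)
  expect_equal(mean(cnt[!same] / 60), mean(Pvec[!same]), tolerance = 0.05)
})

test_that("community labels copy with probability p", {
  prCopy <- tsbmParams("community_label", n = 50, layers = 6, k = 3, p = 1,
                       mu = 0.1, thetaHet = FALSE)
  real <- generateTSBM(prCopy, seed = 2)
  expect_true(all(apply(real@labels, 2, function(x) length(unique(x)) == 1)))

  agree <- function(p, k, seed) {
    pr <- tsbmParams("community_label", n = 400, layers = 26, k = k, p = p,
                     mu = 0.1, thetaHet = FALSE)
    lab <- generateTSBM(pr, seed)@labels
    mean(lab[-1, ] == lab[-26, ])
  }
  expect_equal(agree(0, 2, 3), 0.5, tolerance = 0.02)       # chance = 1/k
  expect_equal(agree(0.8, 5, 4), 0.8 + 0.2 / 5, tolerance = 0.02)
})

test_that("edge states copy with probability p and stay stationary", {
  prC <- tsbmParams("edge_correlated", n = 40, layers = 5, k = 2, p = 1,
                    mu = 0.1, thetaHet = FALSE)
  real <- generateTSBM(prC, seed = 6)
  for (t in 2:5)
    expect_equal(edgeSet(getLayer(real@net, t)),
                 edgeSet(getLayer(real@net, 1)))

  pr <- tsbmParams("edge_correlated", n = 200, layers = 10, k = 5, p = 0.8,
                   mu = 0.1, c = 10, thetaHet = FALSE)
  real <- generateTSBM(pr, seed = 7)
  Pvec <- seqstack:::blockProbabilityVec(real@params, real@labels[1, ])
  surv <- sapply(2:10, function(t) {
    before <- seqstack:::edgeDyadIndices(getLayer(real@net, t - 1), 200)
    after <- seqstack:::edgeDyadIndices(getLayer(real@net, t), 200)
    c(mean(before %in% after), mean(Pvec[before]))
  })
  expect_equal(mean(surv[1, ]), 0.8 + 0.2 * mean(surv[2, ]),
               tolerance = 0.02)
  dens <- sapply(1:10, function(t) igraph::ecount(getLayer(real@net, t)))
  expect_lt(stats::sd(dens) / mean(dens), 0.05)   # no drift in density
})

test_that("mean degree calibrates to c when the cap is inactive", {
  for (k in c(1L, 5L, 15L)) {
    # constant theta keeps every dyad probability below the cap on the grid
    pr <- tsbmParams("edge_correlated", n = 200, layers = 10, k = k,
                     p = 0.7, mu = 0.2, c = 10, thetaHet = FALSE)
    real <- generateTSBM(pr, seed = 10 + k)
    md <- mean(sapply(1:10, function(t)
      mean(igraph::degree(getLayer(real@net, t)))))
    expect_equal(md, 10, tolerance = 0.05)
  }
})

test_that("oracle scores condition on the realized latent state", {
  # between-block probability is (c/n) mu = (5/30) * 0.6 = 0.1
  pr <- tsbmParams("edge_correlated", n = 30, layers = 4, k = 2, p = 0.8,
                   mu = 0.6, c = 5, thetaHet = FALSE)
  real <- generateTSBM(pr, seed = 3)
  orc <- oracleScores(real)
  Pvec <- seqstack:::blockProbabilityVec(real@params, real@labels[1, ])
  prev <- logical(choose(30, 2))
  prev[seqstack:::edgeDyadIndices(getLayer(real@net, 3), 30)] <- TRUE
  expect_equal(oracleProbs(orc), 0.8 * prev + 0.2 * Pvec)
  # a dyad with P = 0.1 that had an edge scores 0.8 + 0.2 * 0.1 = 0.82
  expect_equal(unique(round(oracleProbs(orc)[prev & abs(Pvec - 0.1) < 1e-12], 10)),
               0.82)

  pr0 <- tsbmParams("edge_correlated", n = 30, layers = 4, k = 2, p = 0,
                    mu = 0.2, c = 5, thetaHet = FALSE)
  real0 <- generateTSBM(pr0, seed = 3)
  expect_equal(oracleProbs(oracleScores(real0)),
               seqstack:::blockProbabilityVec(real0@params, real0@labels[1, ]))

  # k = 1 with constant theta: the oracle is uninformative
  prK <- tsbmParams("community_label", n = 20, layers = 3, k = 1, mu = 0.2,
                    c = 4, thetaHet = FALSE)
  realK <- generateTSBM(prK, seed = 1)
  expect_equal(length(unique(oracleProbs(oracleScores(realK)))), 1L)
})

test_that("expected oracle AUC matches exact enumeration", {
  expect_equal(expectedOracleAUC(rep(0.3, 10)), 0.5)
  expect_equal(expectedOracleAUC(c(0.9, 0.1)),
               bruteExpectedOracleAUC(c(0.9, 0.1)))
  set.seed(8)
  for (rep in 1:5) {
    P <- runif(sample(2:5, 1))
    expect_equal(expectedOracleAUC(P), bruteExpectedOracleAUC(P),
                 tolerance = 1e-12)
  }
  # with ties
  P <- c(0.2, 0.2, 0.7, 0.7, 0.5)
  expect_equal(expectedOracleAUC(P), bruteExpectedOracleAUC(P),
               tolerance = 1e-12)
})

test_that("expected oracle AUC is monotone in p and mu", {
  auc <- function(p, mu) {
    pr <- tsbmParams("edge_correlated", n = 100, layers = 4, k = 5, p = p,
                     mu = mu, c = 10, thetaHet = FALSE)
    mean(sapply(1:3, function(s)
      expectedOracleAUC(oracleScores(generateTSBM(pr, seed = s)))))
  }
  expect_gte(auc(0.8, 0.2), auc(0.6, 0.2))
  expect_gte(auc(0.7, 0.1), auc(0.7, 0.3))
})

test_that("the synthetic grid enumerates 45 parameter sets per variant", {
  gridCL <- parameterGrid("community_label")
  gridEC <- parameterGrid("edge_correlated")
  expect_length(gridCL, 45L)
  expect_length(gridEC, 45L)
  expect_length(c(gridCL, gridEC), 90L)
  expect_true(all(vapply(gridCL, function(x) x@n == 200L, logical(1))))
  expect_true(all(vapply(gridCL, function(x) x@layers == 10L, logical(1))))
  expect_setequal(unique(vapply(gridCL, function(x) x@p, numeric(1))),
                  c(0.9, 0.8, 0.7))
  expect_setequal(unique(vapply(gridEC, function(x) x@p, numeric(1))),
                  c(0.8, 0.7, 0.6))
  expect_setequal(unique(vapply(gridEC, function(x) x@k, numeric(1))),
                  c(1, 2, 5, 10, 15))
})

test_that("theta is drawn once, normalized, and carried in the realization", {
  pr <- tsbmParams("edge_correlated", n = 50, layers = 3, k = 2)
  expect_length(pr@theta, 0L)
  expect_error(blockProbability(pr, rep(1L, 50)), "theta")
  real <- generateTSBM(pr, seed = 9)
  th <- real@params@theta
  expect_length(th, 50L)
  expect_equal(mean(th), 1, tolerance = 1e-12)
  expect_true(all(th > 0.3 & th < 2))
  # same seed, same realization
  real2 <- generateTSBM(pr, seed = 9)
  expect_identical(real@params@theta, real2@params@theta)
  expect_equal(edgeSet(getLayer(real@net, 3)), edgeSet(getLayer(real2@net, 3)))
})
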