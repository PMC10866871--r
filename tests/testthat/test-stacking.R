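test_that("dyad folds are stratified with near-equal counts", {
  set.seed(2)
  target <- igraph::sample_gnp(200, 0.05)
  fold <- partitionDyads(target, 5, seed = 42)
  expect_length(fold, 19900L)
  expect_true(all(abs(table(fold) - 3980) <= 1))
  isEdge <- logical(19900)
  isEdge[seqstack:::edgeDyadIndices(target, 200)] <- TRUE
  edgeCounts <- table(fold[isEdge])
  expect_lte(diff(range(edgeCounts)), 1)
  nonCounts <- table(fold[!isEdge])
  expect_lte(diff(range(nonCounts)), 1)

  # 10 edges over 5 folds: exactly 2 each
  g10 <- graphFromEdges0(20, cbind(0:9, 10:19))
  f10 <- partitionDyads(g10, 5, seed = 1)
  isE <- logical(choose(20, 2))
  isE[seqstack:::edgeDyadIndices(g10, 20)] <- TRUE
  expect_true(all(table(f10[isE]) == 2))

  expect_identical(partitionDyads(target, 5, seed = 7),
                   partitionDyads(target, 5, seed = 7))
  expect_false(identical(partitionDyads(target, 5, seed = 7),
                         partitionDyads(target, 5, seed = 8)))
})

test_that("balanced sampling draws uniformly with replacement", {
  g <- graphFromEdges0(4, rbind(c(0, 1)))
  # allowed = 1 edge + 1 non-edge: forced duplication
  allowed <- c(dyadIndex(1, 2, 4), dyadIndex(3, 4, 4))
  s <- sampleBalancedDyads(g, allowed, 5, seed = 1)
  expect_length(s$dyadIdx, 10L)
  expect_equal(sum(s$y), 5L)
  expect_true(all(s$dyadIdx[s$y == 1] == dyadIndex(1, 2, 4)))

  expect_error(sampleBalancedDyads(g, dyadIndex(3, 4, 4), 2, seed = 1),
               "no edges")
  expect_error(sampleBalancedDyads(g, dyadIndex(1, 2, 4), 2, seed = 1),
               "no non-edges")

  # empirical frequency of each of 5 allowed edges ~ 0.2
  g5 <- graphFromEdges0(12, cbind(0:4, 5:9))
  allowed5 <- seq_len(choose(12, 2))
  s <- sampleBalancedDyads(g5, allowed5, 50000, seed = 9)
  freq <- table(s$dyadIdx[s$y == 1]) / 50000
  expect_length(freq, 5L)
  expect_true(all(abs(freq - 0.2) < 0.01))
})

test_that("masking keeps exactly the training-fold edges", {
  set.seed(4)
  g <- igraph::sample_gnp(40, 0.1)
  D <- choose(40, 2)
  expect_equal(edgeSet(maskToObserved(g, seq_len(D))), edgeSet(g))
  expect_equal(igraph::ecount(maskToObserved(g, integer(0))), 0L)
  keep <- sample.int(D, 300)
  masked <- maskToObserved(g, keep)
  eidx <- seqstack:::edgeDyadIndices(g, 40)
  expect_setequal(seqstack:::edgeDyadIndices(masked, 40),
                  eidx[eidx %in% keep])
})

test_that("design shapes follow the u/q bookkeeping exactly", {
  net <- makeErdosNet(40, 7, 0.1, seed = 8)
  for (setting in c("completely_unobserved", "partially_observed")) {
    cfg <- stackingConfig(u = 6, q = 3, setting = setting, nPos = 30,
                          seed = 5, numTrees = 50)
    fold <- partitionDyads(getLayer(net, 7), 5, seed = 1)
    tr <- buildTrainingDesign(net, cfg, fold, testFold = 1)
    te <- buildTestDesign(net, cfg, fold, testFold = 1)
    partial <- setting == "partially_observed"
    expect_equal(length(unique(tr@groupId)), 3L + partial)
    expect_equal(nrow(tr@X), (3L + partial) * 60L)
    expect_equal(ncol(tr@X), 41L * (3L + partial))
    expect_equal(ncol(te@X), ncol(tr@X))
    expect_equal(nrow(te@X), 60L)
    expect_identical(colnames(tr@X), colnames(te@X))
    # test rows come from the held-out fold, training rows never do
    teIdx <- dyadIndex(te@dyads[, 1], te@dyads[, 2], 40)
    expect_true(all(fold[teIdx] == 1L))
    trIdx <- dyadIndex(tr@dyads[, 1], tr@dyads[, 2], 40)
    expect_true(all(fold[trIdx] != 1L))
    # balance within every group
    expect_true(all(tapply(tr@y, tr@groupId, mean) == 0.5))
  }
  # minimum legal history: u = q + 1 gives a single group
  cfgMin <- stackingConfig(u = 4, q = 3, nPos = 20, seed = 2)
  netMin <- makeErdosNet(30, 5, 0.15, seed = 3)
  foldMin <- partitionDyads(getLayer(netMin, 5), 5, seed = 1)
  trMin <- buildTrainingDesign(netMin, cfgMin, foldMin, 1)
  expect_equal(length(unique(trMin@groupId)), 1L)
})

test_that("designs are reproducible and leak no test-fold edges", {
  net <- makeErdosNet(40, 7, 0.1, seed = 12)
  cfg <- stackingConfig(u = 6, q = 3, setting = "partially_observed",
                        nPos = 40, seed = 77)
  fold <- partitionDyads(getLayer(net, 7), 5, seed = 3)
  tr1 <- buildTrainingDesign(net, cfg, fold, 2)
  tr2 <- buildTrainingDesign(net, cfg, fold, 2)
  expect_identical(tr1@X, tr2@X)
  expect_identical(tr1@dyads, tr2@dyads)

  # deleting every test-fold edge of the target layer must leave all
  # feature values of the test design untouched (labels aside)
  target <- getLayer(net, 7)
  testIdx <- which(fold == 2)
  eidx <- seqstack:::edgeDyadIndices(target, 40)
  doomed <- eidx[eidx %in% testIdx]
  gDel <- maskToObserved(target, setdiff(seq_len(choose(40, 2)), testIdx))
  netDel <- temporalNetwork(c(lapply(1:6, getLayer, x = net), list(gDel)),
                            n = 40)
  dyadIdx <- sort(c(sample(testIdx, 50)))
  teA <- buildTestDesign(net, cfg, fold, 2, dyadIdx = dyadIdx)
  teB <- buildTestDesign(netDel, cfg, fold, 2, dyadIdx = dyadIdx)
  expect_identical(teA@X, teB@X)
  expect_gt(sum(teA@y), sum(teB@y) - 1)  # labels do change (all 0 after)
  expect_true(all(teB@y == 0))
  # training design is untouched as well
  trDel <- buildTrainingDesign(netDel, cfg, fold, 2)
  expect_identical(tr1@X, trDel@X)
})

test_that("the stacker learns separable designs and normalizes importances", {
  set.seed(6)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(signal = y + 0.001 * rnorm(n),
             noise1 = rnorm(n), noise2 = rnorm(n))
  design <- new("LabeledDesign", X = X, y = y,
                dyads = matrix(1L, n, 2), groupId = rep(1L, n),
                setting = "completely_unobserved")
  cfg <- stackingConfig(nPos = 10, numTrees = 100, seed = 4)
  fit <- trainStacker(design, cfg, seed = 11)
  expect_equal(sum(fit$importance), 1, tolerance = 1e-9)
  expect_equal(names(which.max(fit$importance)), "signal")
  pred <- predictStacker(fit, X)
  expect_equal(aucScore(pred, y), 1)

  bad <- new("LabeledDesign", X = X, y = rep(1L, n),
             dyads = matrix(1L, n, 2), groupId = rep(1L, n),
             setting = "completely_unobserved")
  expect_error(trainStacker(bad, cfg), "single class")

  # the optional F-measure grid search also returns a working fit
  cfgT <- stackingConfig(nPos = 10, numTrees = 100, seed = 4, tune = TRUE)
  fitT <- trainStacker(design, cfgT, seed = 11)
  expect_equal(aucScore(predictStacker(fitT, X), y), 1)
})

test_that("pure-noise features give chance-level AUC", {
  set.seed(31)
  aucs <- replicate(20, {
    n <- 160
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    design <- new("LabeledDesign", X = X, y = y,
                  dyads = matrix(1L, n, 2), groupId = rep(1L, n),
                  setting = "completely_unobserved")
    cfg <- stackingConfig(nPos = 10, numTrees = 60,
                          seed = sample.int(1e6, 1))
    fit <- trainStacker(design, cfg, seed = sample.int(1e6, 1))
    Xnew <- matrix(rnorm(n * 6), n, 6, dimnames = dimnames(X))
    aucScore(predictStacker(fit, Xnew), y)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
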