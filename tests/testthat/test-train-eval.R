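# Preprocessing, learning-rate schedule, stratified CV, fitting, metrics
# and throughput.

test_that("preprocessing resizes, rescales and flips as configured", {
  img <- generateBaseFrame(3L, 96, 48)          # H x W on the [0, 255] scale
  out <- preprocessImage(img, 64L)
  expect_equal(dim(out), c(64L, 64L, 3L))
  expect_true(all(out >= 0 & out <= 1))

  # flip twice with a forced flip returns the resized original
  once <- preprocessImage(img, 64L, flip = TRUE)
  twice <- preprocessImage(once * 255, 64L, flip = TRUE)
  expect_equal(twice, out, tolerance = 1e-12)

  # flip probability zero is deterministic beyond the resize
  expect_identical(preprocessImage(img, 64L, train = TRUE, flipProb = 0),
                   out)
})

test_that("the exponential schedule matches its closed form", {
  expect_equal(exponentialLR(0), 0.001)
  expect_equal(exponentialLR(7, decay = 1.0), 0.001)
  expect_equal(exponentialLR(2, decay = 0.9), 0.001 * 0.81)
  expect_error(exponentialLR(-1), ">= 0")
})

test_that("metrics follow the Acc/Sens closed forms with smoke positive", {
  r <- confusionMetrics(3, 1, 1, 5)
  expect_identical(reportAccuracy(r), 0.8)
  expect_identical(reportSensitivity(r), 0.75)
  expect_equal(sum(reportCounts(r)), 10L)

  perfect <- confusionMetrics(240, 0, 0, 960)
  expect_identical(reportAccuracy(perfect), 1)
  expect_identical(reportSensitivity(perfect), 1)

  allNeg <- confusionMetrics(0, 0, 240, 960)
  expect_identical(reportAccuracy(allNeg), 0.8)
  expect_identical(reportSensitivity(allNeg), 0)

  expect_warning(noPos <- confusionMetrics(0, 2, 0, 8), "undefined")
  expect_true(is.nan(reportSensitivity(noPos)))

  set.seed(101)
  for (i in 1:20) {
    ct <- sample(0:50, 4, replace = TRUE); ct[1] <- ct[1] + 1L
    r <- confusionMetrics(ct[1], ct[2], ct[3], ct[4])
    expect_equal(reportAccuracy(r), (ct[1] + ct[4]) / sum(ct))
    expect_equal(reportSensitivity(r), ct[1] / (ct[1] + ct[3]))
    expect_equal(sum(reportCounts(r)), sum(ct))
  }
})

test_that("stratified folds preserve the label ratio and the seed", {
  y <- rep(c("smoke", "smoke_free"), c(8, 32))
  f1 <- endosmoke:::stratifiedFolds(y, 2L, seed = 5L)
  expect_equal(unname(table(f1)), c(20L, 20L), ignore_attr = TRUE)
  for (k in 1:2)
    expect_equal(sum(y[f1 == k] == "smoke_free") / sum(y[f1 == k] == "smoke"),
                 4)
  f2 <- endosmoke:::stratifiedFolds(y, 2L, seed = 5L)
  expect_identical(f1, f2)
  expect_false(identical(f1, endosmoke:::stratifiedFolds(y, 2L, seed = 6L)))
})

test_that("fitting reduces the loss on a small synthetic task", {
  ds <- makeImageSet(80L, size = 48L, seed = 7L)
  m <- initModel(tinyConfig(C = 16L, depth = 1L, input = 48L,
                            kernels = c(3L, 1L)), seed = 7)
  fit <- fitModel(m, ds$x, ds$y, epochs = 3L, batchSize = 16L, seed = 7L)
  expect_lt(tail(fit$log$loss, 1), fit$log$loss[1])
  expect_true(isTRUE(fit$model@state$statsFrozen))
  expect_equal(fit$log$lr, 0.001 * 0.9^(0:2))
  expect_error(fitModel(m, ds$x, ds$y, batchSize = 128L), "smaller")
})

test_that("cross-validated training yields fold metrics and checkpoints", {
  md <- sharedTinyDataset()
  cfg <- trainConfig(inputSize = 64L, epochs = 1L, folds = 2L,
                     batchSize = 8L, seed = 3L,
                     model = tinyConfig(C = 8L, depth = 1L, input = 64L))
  outDir <- tempfile()
  res <- trainModel(cfg, md, outDir = outDir)
  expect_equal(nrow(res$foldMetrics), 2L)
  expect_equal(res$foldMetrics$n, c(20L, 20L))
  expect_true(all(file.exists(file.path(outDir,
                                        c("fold01.ckpt", "fold02.ckpt",
                                          "final.ckpt")))))
  expect_equal(length(res$foldAssignments), 40L)
  # assignments reproduce from the config seed
  y <- manifestRecords(md)$label[manifestRecords(md)$split == "train"]
  expect_identical(unname(res$foldAssignments),
                   endosmoke:::stratifiedFolds(y, 2L, seed = 3L))
  unlink(outDir, recursive = TRUE)
})

test_that("evaluation is invariant to ordering and batch size", {
  ds <- makeImageSet(30L, size = 64L, seed = 9L)
  m <- freezeNorm(initModel(tinyConfig(C = 8L, depth = 1L, input = 64L),
                            seed = 9))
  r1 <- endosmoke:::evaluateArrays(m, ds$x, ds$y, batchSize = 7L)
  r2 <- endosmoke:::evaluateArrays(m, ds$x, ds$y, batchSize = 64L)
  expect_identical(reportCounts(r1), reportCounts(r2))
  perm <- sample(30L)
  r3 <- endosmoke:::evaluateArrays(m, ds$x[, , , perm], ds$y[perm])
  expect_identical(reportCounts(r1), reportCounts(r3))
})

test_that("manifest evaluation reports counts that sum to the split size", {
  md <- sharedTinyDataset()
  m <- freezeNorm(initModel(tinyConfig(C = 8L, depth = 1L, input = 64L),
                            seed = 10))
  r <- evaluateModel(m, md, split = "test")
  expect_equal(sum(reportCounts(r)), 10L)
  expect_error(evaluateModel(m, md, split = "nope"), "no images")
})

test_that("metrics JSON carries the confusion counts and rates", {
  r <- confusionMetrics(3, 1, 1, 5)
  p <- tempfile(fileext = ".json")
  writeMetricsJSON(r, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$accuracy, 0.8)
  expect_equal(j$sensitivity, 0.75)
  expect_equal(j$tp, 3L)
  expect_equal(j$tn, 5L)
  unlink(p)
})

test_that("throughput measurement validates inputs and favours fusion", {
  m <- freezeNorm(initModel(tinyConfig(C = 32L, depth = 6L, input = 64L),
                            seed = 11))
  expect_error(measureThroughput(m, nImages = 0L), "positive")
  tTrain <- measureThroughput(m, nImages = 16L, reps = 5L)
  tFused <- measureThroughput(deployModel(m), nImages = 16L, reps = 5L)
  expect_gt(tTrain, 0)
  expect_gt(tFused, tTrain * 0.95)   # direction, with a small timing margin
})
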