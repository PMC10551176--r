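# Structural re-parameterization: norm folding, kernel embedding, block
# fusion, the brute-force oracle, and whole-model deployment.

test_that("foldNorm folds inference normalization into the kernel exactly", {
  k <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  f <- foldNorm(k, gamma = c(1, 1), beta = c(0, 0), mean = c(0, 0),
                var = c(1, 1), eps = 0)
  expect_equal(f$kernel, k)
  expect_equal(f$bias, c(0, 0))

  f0 <- foldNorm(k, gamma = c(0, 0), beta = c(2, -1), mean = rnorm(2),
                 var = c(1, 1), eps = 0)
  expect_equal(max(abs(f0$kernel)), 0)
  expect_equal(f0$bias, c(2, -1))

  set.seed(31)
  C <- 3L
  k <- array(rnorm(5 * 5 * C), c(5, 5, C))
  g <- runif(C, 0.5, 2); b <- rnorm(C); mu <- rnorm(C); v <- runif(C, 0.1, 2)
  f <- foldNorm(k, g, b, mu, v, eps = 1e-5)
  for (i in 1:10) {
    x <- array(rnorm(8 * 8 * C), c(8, 8, C))
    pre <- bruteDWConv(x, k)
    post <- sweep(sweep(pre, 3, sqrt(v + 1e-5), `/`), 3, mu / sqrt(v + 1e-5))
    post <- sweep(sweep(post, 3, g, `*`), 3, b, `+`)
    folded <- bruteDWConv(x, f$kernel, f$bias)
    expect_lt(max(abs(post - folded)), 1e-6)
  }
  expect_error(foldNorm(k, g, b, mu, var = rep(-1, C), eps = 0),
               "variance")
})

test_that("embedKernel centres kernels and maps identity to the Dirac", {
  k3 <- array(seq_len(9), c(3, 3, 1))
  e <- embedKernel(k3, 7)
  expect_equal(e[3:5, 3:5, 1], k3[, , 1])
  e0 <- e; e0[3:5, 3:5, ] <- 0
  expect_equal(max(abs(e0)), 0)

  d <- embedKernel(array(1, c(1, 1, 2)), 7)
  expect_equal(d[4, 4, ], c(1, 1))
  expect_equal(sum(d != 0), 2)

  expect_identical(embedKernel(k3, 3), k3)
  expect_error(embedKernel(k3, 6), "odd")
  expect_error(embedKernel(array(0, c(5, 5, 1)), 3), "at least")
})

test_that("fuseBlock collapses trivial branch combinations to the Dirac", {
  C <- 4L
  pId <- mixerBlockParams(list(array(0, c(3, 3, C))), list(identityBN(C)),
                          includeIdentity = TRUE, eps = 0)
  f <- fuseBlock(pId)
  expect_equal(f@kernel[2, 2, ], rep(1, C))
  expect_equal(sum(f@kernel != 0), C)
  expect_equal(f@bias, numeric(C))
  x <- array(rnorm(6 * 6 * C), c(6, 6, C))
  expect_equal(tokenMixer(x, f), x, tolerance = 1e-12)

  pZ <- mixerBlockParams(list(array(0, c(7, 7, C)), array(0, c(3, 3, C))),
                         list(identityBN(C), identityBN(C)),
                         includeIdentity = TRUE, eps = 0)
  fz <- fuseBlock(pZ)
  expect_equal(fz@kernel[4, 4, ], rep(1, C))
  expect_equal(sum(fz@kernel != 0), C)
})

test_that("fused and multi-branch mixers agree on random instantiations", {
  set.seed(41)
  for (rep in 1:6) {
    C <- sample(c(2L, 4L, 8L), 1)
    p <- randomMixerParams(C, seed = 100 + rep)
    f <- fuseBlock(p)
    x <- array(rnorm(9 * 9 * C), c(9, 9, C))
    expect_lt(max(abs(tokenMixer(x, p) - tokenMixer(x, f))), 1e-5)
  }
})

test_that("fusion is idempotent", {
  p <- randomMixerParams(4L, seed = 2)
  f <- fuseBlock(p)
  expect_identical(fuseBlock(f), f)
})

test_that("fused convolution matches the brute-force direct summation", {
  set.seed(51)
  for (rep in 1:5) {
    p <- randomMixerParams(1L, kernelSizes = c(5L, 3L), seed = 200 + rep)
    f <- fuseBlock(p)
    x <- array(rnorm(5 * 5), c(5, 5, 1))
    viaPackage <- tokenMixer(x, f)
    viaBrute <- bruteDWConv(x, f@kernel, f@bias)
    expect_lt(max(abs(viaPackage - viaBrute)), 1e-10)
    # and the brute-force fused path reproduces the multi-branch sum
    expect_lt(max(abs(viaBrute - tokenMixer(x, p))), 1e-10)
  }
})

test_that("deployment preserves logits and labels and sheds parameters", {
  m <- freezeNorm(initModel(tinyConfig(C = 16L, depth = 2L, input = 64L),
                            seed = 3))
  d <- deployModel(m)
  expect_equal(modelTopology(d), "deployed")

  set.seed(61)
  x <- array(runif(64 * 64 * 3 * 10), c(64, 64, 3, 10))
  expect_lt(max(abs(modelLogits(m, x) - modelLogits(d, x))), 1e-4)

  x100 <- array(runif(64 * 64 * 3 * 100), c(64, 64, 3, 100))
  l1 <- modelLogits(m, x100); l2 <- modelLogits(d, x100)
  expect_identical(max.col(l1, ties.method = "first"),
                   max.col(l2, ties.method = "first"))

  expect_lt(nParameters(d, "fused"), nParameters(m, "\\.mix\\."))
})

test_that("deployment refuses unfrozen statistics and double fusion", {
  m <- initModel(tinyConfig(C = 8L, depth = 1L), seed = 1)
  expect_error(deployModel(m), "frozen")
  d <- deployModel(freezeNorm(m))
  expect_error(deployModel(d), "already deployed")
})

test_that("checkpoints round-trip and fused checkpoints refuse re-fusing", {
  m <- freezeNorm(initModel(tinyConfig(C = 8L, depth = 1L), seed = 4))
  p1 <- tempfile(fileext = ".ckpt"); p2 <- tempfile(fileext = ".ckpt")
  saveCheckpoint(m, p1)
  back <- loadCheckpoint(p1)
  expect_equal(back@params, m@params)
  expect_equal(modelTopology(back), "train")
  fuseCheckpoint(p1, p2)
  expect_equal(modelTopology(loadCheckpoint(p2)), "deployed")
  expect_error(fuseCheckpoint(p2, tempfile()), "already deployed")
  unlink(c(p1, p2))
})
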