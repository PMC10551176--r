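# Encoder: dimension interchange, the multi-branch token mixer, block
# composition, and the residual-identity limit.

zeroEncoderModel <- function(depth = 3L, C = 16L, input = 64L) {
  m <- initModel(tinyConfig(C = C, depth = depth, input = input), seed = 1)
  for (nm in grep("^enc\\.", names(m@params), value = TRUE))
    m@params[[nm]] <- m@params[[nm]] * 0
  m
}

randomSeq <- function(m, seed = 1) {
  set.seed(seed)
  sz <- m@config@inputSize
  tokenize(array(runif(sz[1] * sz[2] * 3), c(sz[1], sz[2], 3)), m)
}

test_that("seq/grid interchange is shape-correct and exactly invertible", {
  s <- tokenSequence(matrix(rnorm(64 * 16), 64, 16), grid = c(8L, 8L))
  map <- seqToGrid(s)
  expect_equal(dim(map), c(8L, 8L, 16L, 1L))
  expect_identical(gridToSeq(map)@tokens, s@tokens)

  # 196 grid tokens at 768 channels (the ViT-compatible layout, class token
  # detached and carried alongside)
  s2 <- tokenSequence(matrix(rnorm(197 * 768), 197, 768), grid = c(14L, 14L),
                      hasClassToken = TRUE)
  map2 <- seqToGrid(s2)
  expect_equal(dim(map2), c(14L, 14L, 768L, 1L))
  expect_equal(dim(attr(map2, "classToken")), c(1L, 768L, 1L))
  expect_identical(gridToSeq(map2)@tokens, s2@tokens)

  s@grid <- NA_integer_
  expect_error(seqToGrid(s), "grid")
})

test_that("the token mixer obeys its identity and Dirac limits", {
  C <- 6L
  map <- array(rnorm(9 * 9 * C), c(9, 9, C))
  zk <- function(k) array(0, c(k, k, C))
  p <- mixerBlockParams(list(zk(7L), zk(3L)),
                        list(identityBN(C), identityBN(C)),
                        includeIdentity = TRUE, eps = 0)
  expect_equal(tokenMixer(map, p), map, tolerance = 1e-12)

  dirac <- zk(3L); dirac[2, 2, ] <- 1
  p2 <- mixerBlockParams(list(dirac), list(identityBN(C)),
                         includeIdentity = FALSE, eps = 0)
  expect_equal(tokenMixer(map, p2), map, tolerance = 1e-12)
})

test_that("the branch sum is linear in the branches", {
  C <- 4L
  map <- array(rnorm(8 * 8 * C), c(8, 8, C))
  set.seed(21)
  k7 <- array(rnorm(7 * 7 * C, sd = 0.3), c(7, 7, C))
  k3 <- array(rnorm(3 * 3 * C, sd = 0.3), c(3, 3, C))
  bn7 <- list(gamma = runif(C, 0.5, 1.5), beta = rnorm(C),
              mean = rnorm(C), var = runif(C, 0.2, 2))
  bn3 <- list(gamma = runif(C, 0.5, 1.5), beta = rnorm(C),
              mean = rnorm(C), var = runif(C, 0.2, 2))
  both <- tokenMixer(map, mixerBlockParams(list(k7, k3), list(bn7, bn3),
                                           includeIdentity = TRUE))
  one <- tokenMixer(map, mixerBlockParams(list(k7), list(bn7),
                                          includeIdentity = TRUE))
  two <- tokenMixer(map, mixerBlockParams(list(k3), list(bn3),
                                          includeIdentity = TRUE))
  # identity contribution appears once per evaluation: subtract the extra map
  expect_equal(both, one + two - map, tolerance = 1e-10)
})

test_that("mixer rejects mismatched channels and oversized kernels", {
  p <- randomMixerParams(8L, seed = 1)
  expect_error(tokenMixer(array(0, c(9, 9, 4)), p), "channel")
  expect_error(tokenMixer(array(0, c(5, 5, 8)), p), "larger")
})

test_that("an encoder block matches its hand-composed sub-updates", {
  m <- initModel(tinyConfig(C = 8L, depth = 1L, input = 64L), seed = 7)
  m <- freezeNorm(m)
  s <- randomSeq(m, seed = 2)
  out <- encoderBlock(s, m, 1L)

  # hand-compose: token mixing with its identity residual, then LN -> MLP
  p <- m@params
  y <- tokenMixer(seqToGrid(s), endosmoke:::blockParamsFromModel(m, 1L))
  ytok <- gridToSeq(y)@tokens
  X <- ytok[, , 1]
  mu <- rowMeans(X); va <- rowMeans(X^2) - mu^2
  Xh <- (X - mu) / sqrt(va + 1e-6)
  Xn <- sweep(sweep(Xh, 2, p[["enc.b1.ln.g"]], `*`), 2,
              p[["enc.b1.ln.b"]], `+`)
  H <- geluActivation(sweep(Xn %*% p[["enc.b1.mlp.W1"]], 2,
                            p[["enc.b1.mlp.b1"]], `+`))
  Z <- sweep(H %*% p[["enc.b1.mlp.W2"]], 2, p[["enc.b1.mlp.b2"]], `+`)
  expect_equal(out@tokens[, , 1], X + Z, tolerance = 1e-10)
})

test_that("blocks preserve shape on arbitrary grids", {
  for (input in list(64L, c(32L, 48L))) {
    m <- initModel(tinyConfig(C = 8L, depth = 1L, input = input,
                              kernels = c(3L, 1L)), seed = 1)
    s <- randomSeq(m)
    out <- encoderBlock(s, m, 1L)
    expect_equal(dim(out@tokens), dim(s@tokens))
    expect_equal(tokenGrid(out), tokenGrid(s))
  }
})

test_that("the encoder with all-zero weights is the identity map", {
  for (depth in c(1L, 4L)) {
    m <- zeroEncoderModel(depth = depth)
    s <- randomSeq(m, seed = depth)
    out <- forwardEncoder(s, m)
    expect_lt(max(abs(out@tokens - s@tokens)), 1e-7)
  }
})

test_that("depth-L forward equals manual nesting of the blocks", {
  m <- initModel(tinyConfig(C = 8L, depth = 2L, input = 64L), seed = 9)
  s <- randomSeq(m, seed = 5)
  viaStack <- forwardEncoder(s, m)
  viaNest <- encoderBlock(encoderBlock(s, m, 1L), m, 2L)
  expect_identical(viaStack@tokens, viaNest@tokens)

  m1 <- initModel(tinyConfig(C = 8L, depth = 1L, input = 64L), seed = 9)
  s1 <- randomSeq(m1, seed = 5)
  expect_identical(forwardEncoder(s1, m1)@tokens,
                   encoderBlock(s1, m1, 1L)@tokens)
})
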