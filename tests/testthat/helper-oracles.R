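# Independent brute-force oracles and small fixtures, implemented with plain
# nested loops so they share no code with the package's conv/fusion paths.

# Direct-summation 2D convolution of one channel plane, stride 1, odd k.
# padmode "zero" or "replicate".
bruteConv1ch <- function(x, k, bias = 0, padmode = "zero") {
  H <- nrow(x); W <- ncol(x); ks <- nrow(k); pad <- (ks - 1) %/% 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- bias
    for (a in seq_len(ks)) for (b in seq_len(ks)) {
      ii <- i - pad + a - 1L; jj <- j - pad + b - 1L
      if (padmode == "replicate") {
        ii <- min(max(ii, 1L), H); jj <- min(max(jj, 1L), W)
        acc <- acc + x[ii, jj] * k[a, b]
      } else if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        acc <- acc + x[ii, jj] * k[a, b]
      }
    }
    out[i, j] <- acc
  }
  out
}

# Depthwise brute-force convolution on an (H, W, C) map.
bruteDWConv <- function(x, K, bias = numeric(dim(K)[3]), padmode = "zero") {
  out <- array(0, dim(x))
  for (c in seq_len(dim(x)[3]))
    out[, , c] <- bruteConv1ch(x[, , c], K[, , c], bias[c], padmode)
  out
}

# Full multi-channel brute-force convolution (Cin -> Cout), stride 1.
bruteConvFull <- function(x, W, b, padmode = "replicate") {
  Cout <- dim(W)[4]
  out <- array(0, c(dim(x)[1], dim(x)[2], Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], dim(x)[1], dim(x)[2])
    for (ci in seq_len(dim(x)[3]))
      acc <- acc + bruteConv1ch(x[, , ci], W[, , ci, co], 0, padmode)
    out[, , co] <- acc
  }
  out
}

# A small model configuration used across tests.
tinyConfig <- function(C = 16L, depth = 2L, input = 64L,
                       kernels = c(7L, 3L), stemChannels = 8L) {
  modelConfig(inputSize = input,
              tokenizer = tokenizerConfig(embedDim = C,
                                          stemChannels = stemChannels),
              encoder = encoderConfig(depth = depth, embedDim = C,
                                      branchKernels = kernels))
}

# Identity batch-norm terms for C channels.
identityBN <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C), mean = numeric(C),
       var = rep(1, C))
}

# In-memory labeled image set at the model input scale ([0, 1]), generated
# with the package's synthesizer but never touching disk.
makeImageSet <- function(n, size = 64L, smokeFrac = 0.2, seed = 1L) {
  set.seed(seed)
  nSmoke <- round(n * smokeFrac)
  y <- rep(c("smoke", "smoke_free"), c(nSmoke, n - nSmoke))
  x <- array(0, c(size, size, 3L, n))
  for (i in seq_len(n)) {
    img <- generateBaseFrame(seed * 10000L + i, size, size)
    if (y[i] == "smoke") {
      sp <- smokeParams(runif(1, 0.3, 1), runif(1, 0.3, 0.9),
                        c(runif(1, 0.2, 0.8) * (size - 1),
                          runif(1, 0.2, 0.8) * (size - 1)),
                        seed = seed * 10000L + i + 1L)
      img <- composeSmoke(img, renderSmoke(sp, size, size))
    }
    x[, , , i] <- img / 255
  }
  list(x = x, y = y)
}

# Tiny on-disk dataset shared by manifest-based tests (built once per run).
.testDataEnv <- new.env(parent = emptyenv())
sharedTinyDataset <- function() {
  if (is.null(.testDataEnv$manifest)) {
    dir <- file.path(tempdir(), "endosmoke-tiny-ds")
    .testDataEnv$manifest <-
      buildSmokeDataset(reducedScaleConfig(total = 50L), dir, seed = 42L)
  }
  .testDataEnv$manifest
}
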