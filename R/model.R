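# Model assembly: convolutional tokenizer -> positional embedding ->
# encoder stack -> sequence pooling -> linear classifier. The forward pass
# keeps per-layer caches so the backward pass can be composed by hand;
# parameters live in one flat named list.

CLASS_LEVELS <- c("smoke", "smoke_free")   # column 1 is the positive class

#' Assemble a model configuration
#'
#' @param inputSize spatial size (scalar or (H, W)) the model expects after
#'   preprocessing.
#' @param tokenizer a [tokenizerConfig()] list.
#' @param encoder an [encoderConfig()] list; its embedDim must match the
#'   tokenizer's.
#' @param nClasses number of classes (2: smoke vs smoke-free).
#' @param hiddenHead use a one-hidden-layer MLP head instead of the default
#'   single linear classifier.
#' @return A [ModelConfig-class].
#' @export
modelConfig <- function(inputSize = 64L, tokenizer = tokenizerConfig(),
                        encoder = encoderConfig(depth = 2L,
                                                embedDim = tokenizer$embedDim),
                        nClasses = 2L, hiddenHead = FALSE) {
  if (length(inputSize) == 1L) inputSize <- rep(inputSize, 2L)
  if (tokenizer$embedDim != encoder$embedDim)
    stop("tokenizer and encoder embedDim differ")
  grid <- stemGrid(tokenizer, inputSize[1], inputSize[2])
  if (max(encoder$branchKernels) > min(grid))
    stop(sprintf("branch kernel %d exceeds the %dx%d token grid",
                 max(encoder$branchKernels), grid[1], grid[2]))
  new("ModelConfig", inputSize = as.integer(inputSize),
      tokenizer = tokenizer, encoder = encoder,
      nClasses = as.integer(nClasses), hiddenHead = isTRUE(hiddenHead))
}

heInit <- function(dims, fanIn) array(rnorm(prod(dims), sd = sqrt(2 / fanIn)), dims)

#' Initialize a model
#'
#' Weights use He-scaled Gaussian initialization; batch-norm terms start as
#' the identity normalization, the positional table and sequence-pool scorer
#' start at zero (uniform attention), and the classifier starts near zero.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer seed; initialization is deterministic given it.
#' @return A [SmokeFormerModel-class] in "train" topology.
#' @export
initModel <- function(config, seed = 1L) {
  tk <- config@tokenizer; ec <- config@encoder
  C <- tk$embedDim; c1 <- tk$stemChannels; k <- tk$kernelSize
  grid <- stemGrid(tk, config@inputSize[1], config@inputSize[2])
  Nt <- prod(grid) + as.integer(tk$classToken)
  withSeed(seed, {
    p <- list()
    p[["tok.conv1.W"]] <- heInit(c(k, k, 3L, c1), k * k * 3)
    p[["tok.conv1.b"]] <- numeric(c1)
    if (tk$includeResidual) {
      p[["tok.resA.W"]] <- heInit(c(k, k, c1, c1), k * k * c1)
      p[["tok.resA.b"]] <- numeric(c1)
      p[["tok.resB.W"]] <- heInit(c(k, k, c1, c1), k * k * c1)
      p[["tok.resB.b"]] <- numeric(c1)
    }
    if (tk$totalStride == 16L) {
      p[["tok.convM.W"]] <- heInit(c(k, k, c1, c1), k * k * c1)
      p[["tok.convM.b"]] <- numeric(c1)
    }
    p[["tok.conv2.W"]] <- heInit(c(k, k, c1, C), k * k * c1)
    p[["tok.conv2.b"]] <- numeric(C)
    if (tk$classToken) p[["tok.cls"]] <- rnorm(C, sd = 0.02)
    p[["tok.pos"]] <- matrix(0, Nt, C)

    st <- list(statsFrozen = FALSE)
    for (l in seq_len(ec$depth)) {
      for (i in seq_along(ec$branchKernels)) {
        kb <- ec$branchKernels[i]
        p[[sprintf("enc.b%d.mix.k%d", l, i)]] <-
          array(rnorm(kb * kb * C, sd = 0.1), c(kb, kb, C))
        p[[sprintf("enc.b%d.mix.g%d", l, i)]] <- rep(1, C)
        p[[sprintf("enc.b%d.mix.b%d", l, i)]] <- numeric(C)
        st[[sprintf("enc.b%d.mix.rm%d", l, i)]] <- numeric(C)
        st[[sprintf("enc.b%d.mix.rv%d", l, i)]] <- rep(1, C)
      }
      p[[sprintf("enc.b%d.ln.g", l)]] <- rep(1, C)
      p[[sprintf("enc.b%d.ln.b", l)]] <- numeric(C)
      H <- ec$mlpRatio * C
      p[[sprintf("enc.b%d.mlp.W1", l)]] <- heInit(c(C, H), C)
      p[[sprintf("enc.b%d.mlp.b1", l)]] <- numeric(H)
      p[[sprintf("enc.b%d.mlp.W2", l)]] <- heInit(c(H, C), H)
      p[[sprintf("enc.b%d.mlp.b2", l)]] <- numeric(C)
    }
    p[["head.pool.w"]] <- numeric(C)
    p[["head.pool.b"]] <- 0
    if (config@hiddenHead) {
      p[["head.hid.W"]] <- heInit(c(C, C), C)
      p[["head.hid.b"]] <- numeric(C)
    }
    p[["head.cls.W"]] <- matrix(rnorm(C * config@nClasses, sd = 0.01),
                                C, config@nClasses)
    p[["head.cls.b"]] <- numeric(config@nClasses)
    new("SmokeFormerModel", config = config, params = p, state = st,
        topology = "train")
  })
}

# ---- sequence pooling -----------------------------------------------------

poolFwd <- function(tokens, w, b) {
  d <- dim(tokens); Nt <- d[1]; C <- d[2]; B <- d[3]
  M <- tokToMat(tokens)
  s <- matrix(M %*% w + b, Nt, B)
  a <- apply(s, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
  a <- matrix(a, Nt, B)
  f <- matrix(0, C, B)
  for (bi in seq_len(B)) f[, bi] <- crossprod(tokens[, , bi, drop = TRUE], a[, bi])
  list(features = f, cache = list(tokens = tokens, a = a, w = w))
}

poolBwd <- function(cache, dfeat) {
  tokens <- cache$tokens; a <- cache$a; w <- cache$w
  d <- dim(tokens); Nt <- d[1]; C <- d[2]; B <- d[3]
  dtok <- array(0, d); dw <- numeric(C); db <- 0
  for (bi in seq_len(B)) {
    Tb <- matrix(tokens[, , bi], Nt, C)
    g <- dfeat[, bi]
    da <- Tb %*% g                          # dL/da_i = g . t_i
    ds <- a[, bi] * (da - sum(a[, bi] * da))
    dtok[, , bi] <- a[, bi] %o% g + ds %*% t(w)
    dw <- dw + crossprod(Tb, ds)[, 1]
    db <- db + sum(ds)
  }
  list(dtok = dtok, dw = dw, db = db)
}

#' Sequence pooling: attention-weighted token averaging
#'
#' A learned scalar score per token is softmax-normalized over the sequence
#' and used to average the tokens into one feature vector; the attention
#' weights sum to 1. With a zero scorer this is plain mean pooling. This
#' replaces class-token slicing: every token, carrying both image content
#' and class evidence, contributes to the pooled embedding.
#'
#' @param seq a [TokenSequence-class] (batch allowed).
#' @param w,b scorer weight vector (length C) and scalar offset.
#' @return A length-C feature vector (or C x B matrix for a batch).
#' @export
sequencePool <- function(seq, w, b = 0) {
  if (nTokens(seq) < 1L) stop("cannot pool an empty token sequence")
  f <- poolFwd(seq@tokens, w, b)$features
  if (ncol(f) == 1L) f[, 1] else f
}

#' Linear classification of a pooled feature vector
#'
#' logits = t(W) feature + b; the label is the argmax and the score its
#' softmax probability.
#'
#' @param feature length-C feature vector.
#' @param W C x 2 weight matrix (columns ordered smoke, smoke_free).
#' @param b length-2 bias.
#' @return A [Prediction-class].
#' @export
classifyFeatures <- function(feature, W, b = numeric(ncol(W))) {
  logits <- drop(crossprod(W, feature)) + b
  names(logits) <- CLASS_LEVELS[seq_along(logits)]
  p <- exp(logits - max(logits)); p <- p / sum(p)
  i <- which.max(logits)
  new("Prediction", logits = logits, label = names(logits)[i],
      score = unname(p[i]))
}

# ---- full forward / backward ----------------------------------------------

modelFwdFull <- function(model, x, training = FALSE) {
  cfg <- model@config
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  B <- dim(x)[4]
  st <- stemFwd(model@params, cfg@tokenizer, x)
  tokens <- st$tokens
  if (cfg@tokenizer$classToken) {
    cls <- array(rep(model@params[["tok.cls"]], B),
                 c(1L, dim(tokens)[2], B))
    tokens <- abind3(cls, tokens)
  }
  tokens <- tokens + c(model@params[["tok.pos"]])
  state <- model@state
  blockCaches <- vector("list", cfg@encoder$depth)
  for (l in seq_len(cfg@encoder$depth)) {
    r <- encBlockFwd(model@params, state, cfg@encoder, l, tokens, st$grid,
                     cfg@tokenizer$classToken, training, model@topology)
    tokens <- r$tokens; state <- r$state; blockCaches[[l]] <- r$cache
  }
  pl <- poolFwd(tokens, model@params[["head.pool.w"]],
                model@params[["head.pool.b"]])
  Fmat <- t(pl$features)                    # (B, C)
  headCache <- list()
  if (cfg@hiddenHead) {
    h1 <- linearFwd(Fmat, model@params[["head.hid.W"]],
                    model@params[["head.hid.b"]])
    hg <- geluFwd(h1$out)
    headCache$h1 <- h1$cache; headCache$hg <- hg$cache
    Fmat <- hg$out
  }
  lg <- linearFwd(Fmat, model@params[["head.cls.W"]],
                  model@params[["head.cls.b"]])
  colnames(lg$out) <- CLASS_LEVELS[seq_len(ncol(lg$out))]
  list(logits = lg$out, state = state,
       caches = list(stem = st, blocks = blockCaches, pool = pl$cache,
                     head = headCache, cls = lg$cache, grid = st$grid, B = B))
}

modelBwd <- function(model, caches, dlogits) {
  cfg <- model@config
  grads <- list()
  bc <- linearBwd(caches$cls, model@params[["head.cls.W"]], dlogits)
  grads[["head.cls.W"]] <- bc$dW; grads[["head.cls.b"]] <- bc$db
  dF <- bc$dx
  if (cfg@hiddenHead) {
    dg <- geluBwd(caches$head$hg, dF)
    bh <- linearBwd(caches$head$h1, model@params[["head.hid.W"]], dg)
    grads[["head.hid.W"]] <- bh$dW; grads[["head.hid.b"]] <- bh$db
    dF <- bh$dx
  }
  pb <- poolBwd(caches$pool, t(dF))
  grads[["head.pool.w"]] <- pb$dw; grads[["head.pool.b"]] <- pb$db
  dtok <- pb$dtok
  for (l in rev(seq_len(cfg@encoder$depth))) {
    bb <- encBlockBwd(model@params, cfg@encoder, l, caches$blocks[[l]], dtok)
    grads <- c(grads, bb$grads)
    dtok <- bb$dx
  }
  grads[["tok.pos"]] <- matrix(rowSums(matrix(dtok, ncol = caches$B)),
                               dim(dtok)[1], dim(dtok)[2])
  if (cfg@tokenizer$classToken) {
    grads[["tok.cls"]] <- rowSums(matrix(dtok[1, , ], ncol = caches$B))
    dtok <- dtok[-1, , , drop = FALSE]
  }
  grads <- c(grads, stemBwd(model@params, cfg@tokenizer, caches$stem$caches,
                            dtok, caches$grid))
  grads
}

#' Compute class logits for a preprocessed image batch
#'
#' @param model a [SmokeFormerModel-class] (either topology).
#' @param x an (H, W, 3) image or (H, W, 3, B) batch at the model's input
#'   size, values in [0, 1].
#' @return A (B, 2) logit matrix with columns smoke, smoke_free.
#' @export
modelLogits <- function(model, x) {
  d <- dim(x)
  if (d[1] != model@config@inputSize[1] || d[2] != model@config@inputSize[2])
    stop(sprintf("input %dx%d does not match the model's %dx%d; preprocess first",
                 d[1], d[2], model@config@inputSize[1],
                 model@config@inputSize[2]))
  modelFwdFull(model, x, training = FALSE)$logits
}

#' End-to-end prediction for one raw image
#'
#' Resizes the image to the model's input size ([preprocessImage()]), runs
#' tokenizer, encoder, sequence pooling and classifier, and returns the
#' predicted label with its softmax score. Works identically for "train" and
#' "deployed" topologies.
#'
#' @param model a [SmokeFormerModel-class].
#' @param image an (H, W, 3) array on the [0, 255] (or [0, 1]) scale.
#' @return A [Prediction-class].
#' @export
predictImage <- function(model, image) {
  x <- preprocessImage(image, model@config@inputSize)
  logits <- modelLogits(model, x)[1, ]
  p <- exp(logits - max(logits)); p <- p / sum(p)
  i <- which.max(logits)
  new("Prediction", logits = logits, label = names(logits)[i],
      score = unname(p[i]))
}

#' Batch prediction over a dataset manifest
#'
#' @param model a [SmokeFormerModel-class].
#' @param manifest a [DatasetManifest-class].
#' @param split optional split filter ("train" or "test").
#' @param outCsv optional path; when given, a CSV `path,label,score` is
#'   written.
#' @return A data.frame with columns path, label, score.
#' @export
predictManifest <- function(model, manifest, split = NULL, outCsv = NULL) {
  rec <- manifestRecords(manifest)
  if (!is.null(split)) rec <- rec[rec$split == split, , drop = FALSE]
  res <- lapply(rec$path, function(p) {
    pr <- predictImage(model, readImageFile(file.path(manifest@dir, p)))
    data.frame(path = p, label = pr@label, score = pr@score)
  })
  out <- do.call(rbind, res)
  if (!is.null(outCsv))
    utils::write.table(out, outCsv, sep = ",", quote = FALSE,
                       row.names = FALSE)
  out
}
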