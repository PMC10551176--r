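# MetaFormer encoder whose token mixer is a multi-branch depthwise
# convolutional block: parallel depthwise convolutions (default 7x7 and 3x3,
# each followed by its own batch normalization) plus an identity branch that
# carries the token-mixing residual — the RepVGG-style fusible family. Each
# block then applies a channel MLP (layer norm -> expand -> GELU -> project)
# inside a second residual. Token mixing is depthwise only; all channel
# mixing lives in the MLP.

#' Encoder configuration
#'
#' @param depth number of encoder blocks L (the full-scale protocol uses 10).
#' @param embedDim channel dimension C of the token sequence.
#' @param mlpRatio expansion factor of the channel MLP (default 4).
#' @param branchKernels odd depthwise kernel sizes of the mixer branches;
#'   the first must be the largest (it sets the fused kernel size).
#' @param includeIdentity include the identity branch (the token-mixing
#'   residual; default TRUE).
#' @param bnMomentum,bnEps batch-normalization running-moment momentum and
#'   variance floor.
#' @return A validated list of encoder settings.
#' @export
encoderConfig <- function(depth = 10L, embedDim = 64L, mlpRatio = 4L,
                          branchKernels = c(7L, 3L), includeIdentity = TRUE,
                          bnMomentum = 0.1, bnEps = 1e-5) {
  if (depth < 1L) stop("depth must be >= 1")
  if (any(branchKernels %% 2L == 0L)) stop("branch kernels must be odd")
  if (max(branchKernels) != branchKernels[1])
    stop("the first branch kernel must be the largest")
  list(depth = as.integer(depth), embedDim = as.integer(embedDim),
       mlpRatio = as.integer(mlpRatio),
       branchKernels = as.integer(branchKernels),
       includeIdentity = isTRUE(includeIdentity),
       bnMomentum = bnMomentum, bnEps = bnEps)
}

#' MixerBlockParams: multi-branch token-mixer weights
#'
#' One depthwise kernel per branch ((k, k, C) arrays, one spatial kernel per
#' channel) with per-branch batch-normalization terms (gamma, beta and the
#' frozen running mean/var), plus the identity-branch flag.
#'
#' @slot kernels list of (k, k, C) depthwise kernels.
#' @slot bn list (same length) of lists with elements gamma, beta, mean, var
#'   (each length C).
#' @slot includeIdentity logical.
#' @slot eps numeric batch-norm variance floor.
#' @export
setClass("MixerBlockParams",
  representation(kernels = "list", bn = "list", includeIdentity = "logical",
                 eps = "numeric"),
  validity = function(object) {
    msg <- character()
    ks <- vapply(object@kernels, function(k) dim(k)[1], integer(1))
    Cs <- vapply(object@kernels, function(k) dim(k)[3], integer(1))
    if (length(object@kernels) != length(object@bn))
      msg <- c(msg, "one bn entry per kernel branch is required")
    if (any(ks %% 2L == 0L)) msg <- c(msg, "kernels must be odd-sized")
    if (length(unique(Cs)) > 1L)
      msg <- c(msg, "all branches must share the channel count")
    for (b in object@bn)
      if (!all(c("gamma", "beta", "mean", "var") %in% names(b)))
        msg <- c(msg, "bn entries need gamma, beta, mean, var")
    if (length(msg)) unique(msg) else TRUE
  })

setMethod("show", "MixerBlockParams", function(object) {
  ks <- vapply(object@kernels, function(k) dim(k)[1], integer(1))
  cat(sprintf("MixerBlockParams: %d channels, branches {%s}%s\n",
              dim(object@kernels[[1]])[3], paste(ks, collapse = ", "),
              if (object@includeIdentity) " + identity" else ""))
})

#' Construct / sample token-mixer block parameters
#'
#' `mixerBlockParams` wraps explicit weights; `randomMixerParams` draws a
#' random instantiation (Gaussian kernels, random positive batch-norm
#' statistics) — convenient for equivalence checks of the
#' re-parameterization.
#'
#' @param kernels list of (k, k, C) depthwise kernels (largest first).
#' @param bn list of per-branch lists with gamma, beta, mean, var.
#' @param includeIdentity include the identity branch.
#' @param eps batch-norm variance floor.
#' @return A [MixerBlockParams-class].
#' @export
mixerBlockParams <- function(kernels, bn, includeIdentity = TRUE,
                             eps = 1e-5) {
  new("MixerBlockParams", kernels = kernels, bn = bn,
      includeIdentity = includeIdentity, eps = eps)
}

#' @rdname mixerBlockParams
#' @param channels channel count C.
#' @param kernelSizes odd kernel sizes, largest first.
#' @param seed RNG seed.
#' @export
randomMixerParams <- function(channels, kernelSizes = c(7L, 3L),
                              includeIdentity = TRUE, seed = 1L,
                              eps = 1e-5) {
  withSeed(seed, {
    kernels <- lapply(kernelSizes, function(k)
      array(rnorm(k * k * channels, sd = 0.3), c(k, k, channels)))
    bn <- lapply(kernelSizes, function(k)
      list(gamma = runif(channels, 0.5, 1.5),
           beta = rnorm(channels, sd = 0.2),
           mean = rnorm(channels, sd = 0.2),
           var = runif(channels, 0.2, 1.5)))
    mixerBlockParams(kernels, bn, includeIdentity, eps)
  })
}

#' Interchange token and spatial-grid layouts
#'
#' `seqToGrid` rearranges an (N, C, B) token sequence into its spatial
#' feature map (Hg, Wg, C, B); a class token (index 1), if present, is
#' detached and carried alongside as the `"classToken"` attribute.
#' `gridToSeq` is the exact inverse: `gridToSeq(seqToGrid(s))` is
#' bit-identical to `s`.
#'
#' @param seq a [TokenSequence-class].
#' @return For `seqToGrid`, the (Hg, Wg, C, B) array; for `gridToSeq`, the
#'   reassembled [TokenSequence-class].
#' @export
seqToGrid <- function(seq) {
  if (length(seq@grid) != 2L || any(is.na(seq@grid)))
    stop("token sequence is missing its spatial grid metadata")
  tok <- seq@tokens
  cls <- NULL
  if (seq@hasClassToken) {
    cls <- tok[1, , , drop = FALSE]
    tok <- tok[-1, , , drop = FALSE]
  }
  d <- dim(tok)
  map <- array(tok, c(seq@grid[1], seq@grid[2], d[2], d[3]))
  attr(map, "classToken") <- cls
  map
}

#' @rdname seqToGrid
#' @param map an (Hg, Wg, C, B) array as produced by `seqToGrid`.
#' @param classToken optional (1, C, B) array overriding the attribute.
#' @export
gridToSeq <- function(map, classToken = attr(map, "classToken")) {
  d <- dim(map)
  tok <- array(map, c(d[1] * d[2], d[3], d[4]))
  if (!is.null(classToken)) tok <- abind3(classToken, tok)
  tokenSequence(tok, c(d[1], d[2]), hasClassToken = !is.null(classToken))
}

# inference-mode batch-norm as a per-channel affine map
bnAffine <- function(bn, eps) {
  scale <- bn$gamma / sqrt(bn$var + eps)
  list(scale = scale, shift = bn$beta - bn$mean * scale)
}

#' Apply a multi-branch token mixer to a feature map
#'
#' Sum over branches of depthwise convolution ("same" zero padding)
#' followed by the branch's normalization (applied with its stored
#' statistics), plus the identity branch when configured. Spatial
#' dimensions are preserved.
#'
#' @param map an (Hg, Wg, C) map or (Hg, Wg, C, B) batch.
#' @param params a [MixerBlockParams-class] (or [FusedMixerParams-class],
#'   in which case the single fused convolution is applied).
#' @return The mixed feature map, same shape as the input.
#' @export
tokenMixer <- function(map, params) {
  single <- length(dim(map)) == 3L
  if (single) map <- array(map, c(dim(map), 1L))
  C <- dim(map)[3]
  if (is(params, "FusedMixerParams")) {
    out <- dwconvFwd(map, params@kernel, params@bias)$out
  } else {
    validObject(params)
    if (dim(params@kernels[[1]])[3] != C)
      stop("channel count of map and mixer parameters differ")
    if (dim(params@kernels[[1]])[1] > min(dim(map)[1:2]))
      stop("branch kernel is larger than the token grid")
    out <- if (params@includeIdentity) map else array(0, dim(map))
    n <- dim(map)[1] * dim(map)[2] * dim(map)[4]
    for (i in seq_along(params@kernels)) {
      z <- dwconvFwd(map, params@kernels[[i]], numeric(C))$out
      af <- bnAffine(params@bn[[i]], params@eps)
      zm <- matrix(aperm(z, c(1, 2, 4, 3)), ncol = C)
      zm <- zm * rep(af$scale, each = n) + rep(af$shift, each = n)
      out <- out + aperm(array(zm, c(dim(map)[1], dim(map)[2], dim(map)[4], C)),
                         c(1, 2, 4, 3))
    }
  }
  if (single) out <- array(out, dim(out)[1:3])
  out
}

# ---- internal training-path forward/backward ------------------------------

mixerParamNames <- function(l, nb) {
  unlist(lapply(seq_len(nb), function(i)
    sprintf("enc.b%d.mix.%s%d", l, c("k", "g", "b"), i)))
}

encBlockParamNames <- function(l, cfg) {
  c(mixerParamNames(l, length(cfg$branchKernels)),
    sprintf("enc.b%d.%s", l,
            c("ln.g", "ln.b", "mlp.W1", "mlp.b1", "mlp.W2", "mlp.b2")))
}

# One encoder block on (Nt, C, B) tokens. The mixer runs on the grid tokens
# only; a class token passes through the mixing stage unchanged (its
# identity path) and joins the channel MLP with all other tokens.
encBlockFwd <- function(params, state, cfg, l, tokens, grid, hasCls,
                        training, topology = "train") {
  d <- dim(tokens); C <- d[2]; B <- d[3]
  cache <- list(hasCls = hasCls, grid = grid, d = d)
  cls <- NULL
  gridTok <- tokens
  if (hasCls) {
    cls <- tokens[1, , , drop = FALSE]
    gridTok <- tokens[-1, , , drop = FALSE]
  }
  map <- array(gridTok, c(grid[1], grid[2], C, B))

  if (topology == "deployed") {
    y <- dwconvFwd(map, params[[sprintf("enc.b%d.fused.K", l)]],
                   params[[sprintf("enc.b%d.fused.b", l)]])$out
  } else {
    y <- if (cfg$includeIdentity) map else array(0, dim(map))
    cache$branches <- list()
    for (i in seq_along(cfg$branchKernels)) {
      kn <- sprintf("enc.b%d.mix.k%d", l, i)
      cv <- dwconvFwd(map, params[[kn]], numeric(C))
      bn <- bnFwd(cv$out, params[[sprintf("enc.b%d.mix.g%d", l, i)]],
                  params[[sprintf("enc.b%d.mix.b%d", l, i)]],
                  state[[sprintf("enc.b%d.mix.rm%d", l, i)]],
                  state[[sprintf("enc.b%d.mix.rv%d", l, i)]],
                  training, cfg$bnMomentum, cfg$bnEps)
      state[[sprintf("enc.b%d.mix.rm%d", l, i)]] <- bn$runMean
      state[[sprintf("enc.b%d.mix.rv%d", l, i)]] <- bn$runVar
      cache$branches[[i]] <- list(conv = cv$cache, bn = bn$cache)
      y <- y + bn$out
    }
  }
  yTok <- array(y, c(grid[1] * grid[2], C, B))
  if (hasCls) yTok <- abind3(cls, yTok)

  X <- tokToMat(yTok)
  ln <- lnFwd(X, params[[sprintf("enc.b%d.ln.g", l)]],
              params[[sprintf("enc.b%d.ln.b", l)]])
  f1 <- linearFwd(ln$out, params[[sprintf("enc.b%d.mlp.W1", l)]],
                  params[[sprintf("enc.b%d.mlp.b1", l)]])
  g <- geluFwd(f1$out)
  f2 <- linearFwd(g$out, params[[sprintf("enc.b%d.mlp.W2", l)]],
                  params[[sprintf("enc.b%d.mlp.b2", l)]])
  out <- yTok + matToTok(f2$out, dim(yTok)[1], B)
  cache$ln <- ln$cache; cache$f1 <- f1$cache; cache$gelu <- g$cache
  cache$f2 <- f2$cache
  list(tokens = out, cache = cache, state = state)
}

encBlockBwd <- function(params, cfg, l, cache, dout) {
  d <- cache$d; C <- d[2]; B <- d[3]
  grads <- list()
  Nt <- dim(dout)[1]
  dm <- tokToMat(dout)
  b2 <- linearBwd(cache$f2, params[[sprintf("enc.b%d.mlp.W2", l)]], dm)
  grads[[sprintf("enc.b%d.mlp.W2", l)]] <- b2$dW
  grads[[sprintf("enc.b%d.mlp.b2", l)]] <- b2$db
  dg <- geluBwd(cache$gelu, b2$dx)
  b1 <- linearBwd(cache$f1, params[[sprintf("enc.b%d.mlp.W1", l)]], dg)
  grads[[sprintf("enc.b%d.mlp.W1", l)]] <- b1$dW
  grads[[sprintf("enc.b%d.mlp.b1", l)]] <- b1$db
  bl <- lnBwd(cache$ln, b1$dx)
  grads[[sprintf("enc.b%d.ln.g", l)]] <- bl$dgamma
  grads[[sprintf("enc.b%d.ln.b", l)]] <- bl$dbeta
  dyTok <- dout + matToTok(bl$dx, Nt, B)      # residual + MLP path

  dcls <- NULL
  if (cache$hasCls) {
    dcls <- dyTok[1, , , drop = FALSE]
    dyTok <- dyTok[-1, , , drop = FALSE]
  }
  dy <- array(dyTok, c(cache$grid[1], cache$grid[2], C, B))
  dmap <- if (cfg$includeIdentity) dy else array(0, dim(dy))
  for (i in seq_along(cfg$branchKernels)) {
    bb <- bnBwd(cache$branches[[i]]$bn, dy)
    grads[[sprintf("enc.b%d.mix.g%d", l, i)]] <- bb$dgamma
    grads[[sprintf("enc.b%d.mix.b%d", l, i)]] <- bb$dbeta
    kn <- sprintf("enc.b%d.mix.k%d", l, i)
    bc <- dwconvBwd(cache$branches[[i]]$conv, params[[kn]], bb$dx)
    grads[[kn]] <- bc$dK
    dmap <- dmap + bc$dx
  }
  dtok <- array(dmap, c(cache$grid[1] * cache$grid[2], C, B))
  if (cache$hasCls) dtok <- abind3(dcls, dtok)
  list(dx = dtok, grads = grads)
}

#' Apply one encoder block / the whole encoder to a token sequence
#'
#' `encoderBlock` runs block `block` of the model on a sequence;
#' `forwardEncoder` applies all `depth` blocks sequentially. Both run in
#' inference mode (frozen normalization statistics) and preserve token count
#' and channel dimension.
#'
#' @param seq a [TokenSequence-class].
#' @param model a [SmokeFormerModel-class].
#' @param block block index in 1..depth.
#' @return The transformed [TokenSequence-class].
#' @export
encoderBlock <- function(seq, model, block = 1L) {
  cfg <- model@config@encoder
  r <- encBlockFwd(model@params, model@state, cfg, block, seq@tokens,
                   seq@grid, seq@hasClassToken, training = FALSE,
                   topology = model@topology)
  tokenSequence(r$tokens, seq@grid, seq@hasClassToken)
}

#' @rdname encoderBlock
#' @export
forwardEncoder <- function(seq, model) {
  cfg <- model@config@encoder
  out <- seq
  for (l in seq_len(cfg$depth)) out <- encoderBlock(out, model, l)
  out
}
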