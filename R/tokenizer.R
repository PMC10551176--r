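# Convolutional tokenizer: replaces large-stride ViT patching with a small
# convolutional stem (conv -> GELU -> maxpool -> residual block -> conv ->
# flatten), then an optional class token and a learnable positional
# embedding. The stem works for any input size at least as large as its
# total stride; the token grid is a pure function of the input size.

#' Tokenizer configuration
#'
#' The stem layout is fixed (conv3x3/s2 -> GELU -> maxpool3x3/s2 ->
#' residual block -> [conv3x3/s2 -> GELU ->] conv3x3/s2 -> flatten); the
#' widths are free. `totalStride` 8 uses three stride-2 stages, 16 inserts a
#' fourth. Stem convolutions use replicate (edge) padding so that a
#' spatially constant field stays constant through the stem.
#'
#' @param embedDim output channels C of the token sequence.
#' @param stemChannels width of the intermediate stem stages.
#' @param totalStride 8 (default, small-scale) or 16 (ViT-B/16-compatible
#'   grid: 224 x 224 input -> 14 x 14 = 196 grid tokens).
#' @param kernelSize odd stem kernel size.
#' @param poolSize,poolStride max-pooling window and stride.
#' @param includeResidual include the ResNet-style residual block.
#' @param classToken prepend a learnable class token (default FALSE: the
#'   sequence-pooling head replaces it; the ViT-compatible 197-token layout
#'   is available by switching it on).
#' @return A validated list of tokenizer settings.
#' @export
tokenizerConfig <- function(embedDim = 64L, stemChannels = 32L,
                            totalStride = 8L, kernelSize = 3L,
                            poolSize = 3L, poolStride = 2L,
                            includeResidual = TRUE, classToken = FALSE) {
  if (embedDim <= 0) stop("embedDim must be positive")
  if (kernelSize %% 2L == 0L) stop("kernel sizes must be odd")
  if (!totalStride %in% c(8L, 16L)) stop("totalStride must be 8 or 16")
  list(embedDim = as.integer(embedDim),
       stemChannels = as.integer(stemChannels),
       totalStride = as.integer(totalStride),
       kernelSize = as.integer(kernelSize), poolSize = as.integer(poolSize),
       poolStride = as.integer(poolStride),
       includeResidual = isTRUE(includeResidual),
       classToken = isTRUE(classToken))
}

#' @rdname tokenizerConfig
#' @export
vitCompatTokenizerConfig <- function() {
  tokenizerConfig(embedDim = 768L, stemChannels = 64L, totalStride = 16L,
                  classToken = TRUE)
}

# output size of one 3x3 stride-2 stage with pad 1
stride2Out <- function(n) (n - 1L) %/% 2L + 1L

stemGrid <- function(cfg, height, width) {
  s <- if (cfg$totalStride == 16L) 4L else 3L
  h <- as.integer(height); w <- as.integer(width)
  for (i in seq_len(s)) { h <- stride2Out(h); w <- stride2Out(w) }
  c(h, w)
}

stemParamNames <- function(cfg) {
  nm <- c("tok.conv1.W", "tok.conv1.b")
  if (cfg$includeResidual)
    nm <- c(nm, "tok.resA.W", "tok.resA.b", "tok.resB.W", "tok.resB.b")
  if (cfg$totalStride == 16L) nm <- c(nm, "tok.convM.W", "tok.convM.b")
  c(nm, "tok.conv2.W", "tok.conv2.b")
}

# Forward pass of the stem on an (H, W, 3, B) batch. Returns grid tokens
# (Ngrid, C, B) plus the caches needed for the backward pass.
stemFwd <- function(params, cfg, x) {
  caches <- list()
  c1 <- convFwd(x, params[["tok.conv1.W"]], params[["tok.conv1.b"]],
                stride = 2L, pad = 1L)
  caches$conv1 <- c1$cache
  g1 <- geluFwd(c1$out); caches$gelu1 <- g1$cache
  p1 <- maxpoolFwd(g1$out, cfg$poolSize, cfg$poolStride, 1L)
  caches$pool <- p1$cache
  h <- p1$out
  if (cfg$includeResidual) {
    rA <- convFwd(h, params[["tok.resA.W"]], params[["tok.resA.b"]],
                  stride = 1L, pad = 1L)
    caches$resA <- rA$cache
    gA <- geluFwd(rA$out); caches$resGelu <- gA$cache
    rB <- convFwd(gA$out, params[["tok.resB.W"]], params[["tok.resB.b"]],
                  stride = 1L, pad = 1L)
    caches$resB <- rB$cache
    h <- h + rB$out
  }
  if (cfg$totalStride == 16L) {
    cM <- convFwd(h, params[["tok.convM.W"]], params[["tok.convM.b"]],
                  stride = 2L, pad = 1L)
    caches$convM <- cM$cache
    gM <- geluFwd(cM$out); caches$geluM <- gM$cache
    h <- gM$out
  }
  c2 <- convFwd(h, params[["tok.conv2.W"]], params[["tok.conv2.b"]],
                stride = 2L, pad = 1L)
  caches$conv2 <- c2$cache
  d <- dim(c2$out)                           # (Hg, Wg, C, B)
  tokens <- array(c2$out, c(d[1] * d[2], d[3], d[4]))
  list(tokens = tokens, grid = c(d[1], d[2]), caches = caches)
}

stemBwd <- function(params, cfg, caches, dtokens, grid) {
  C <- dim(dtokens)[2]; B <- dim(dtokens)[3]
  dmap <- array(dtokens, c(grid[1], grid[2], C, B))
  grads <- list()
  b2 <- convBwd(caches$conv2, params[["tok.conv2.W"]], dmap)
  grads[["tok.conv2.W"]] <- b2$dW; grads[["tok.conv2.b"]] <- b2$db
  dh <- b2$dx
  if (cfg$totalStride == 16L) {
    dgM <- geluBwd(caches$geluM, dh)
    bM <- convBwd(caches$convM, params[["tok.convM.W"]], dgM)
    grads[["tok.convM.W"]] <- bM$dW; grads[["tok.convM.b"]] <- bM$db
    dh <- bM$dx
  }
  if (cfg$includeResidual) {
    bB <- convBwd(caches$resB, params[["tok.resB.W"]], dh)
    grads[["tok.resB.W"]] <- bB$dW; grads[["tok.resB.b"]] <- bB$db
    dgA <- geluBwd(caches$resGelu, bB$dx)
    bA <- convBwd(caches$resA, params[["tok.resA.W"]], dgA)
    grads[["tok.resA.W"]] <- bA$dW; grads[["tok.resA.b"]] <- bA$db
    dh <- dh + bA$dx                       # shortcut + branch
  }
  dp <- maxpoolBwd(caches$pool, dh)
  dg1 <- geluBwd(caches$gelu1, dp)
  b1 <- convBwd(caches$conv1, params[["tok.conv1.W"]], dg1)
  grads[["tok.conv1.W"]] <- b1$dW; grads[["tok.conv1.b"]] <- b1$db
  grads
}

#' Tokenize an image batch
#'
#' Runs the convolutional stem and flattens the spatial grid to a token
#' sequence; when the configuration asks for a class token it is prepended
#' at index 1. Positional embedding is a separate step
#' ([addPositionalEmbedding()]).
#'
#' @param x an (H, W, 3) image or (H, W, 3, B) batch; any spatial size at
#'   least the total stride is accepted.
#' @param model a [SmokeFormerModel-class] supplying the stem weights.
#' @return A [TokenSequence-class].
#' @export
tokenize <- function(x, model) {
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  cfg <- model@config@tokenizer
  d <- dim(x)
  if (d[1] < cfg$totalStride || d[2] < cfg$totalStride)
    stop(sprintf("image %dx%d is too small: the stem needs at least %dx%d",
                 d[1], d[2], cfg$totalStride, cfg$totalStride))
  st <- stemFwd(model@params, cfg, x)
  tokens <- st$tokens
  if (cfg$classToken) {
    B <- dim(tokens)[3]
    cls <- array(rep(model@params[["tok.cls"]], B),
                 c(1L, dim(tokens)[2], B))
    tokens <- abind3(cls, tokens)
  }
  tokenSequence(tokens, st$grid, hasClassToken = cfg$classToken)
}

# bind two (n, C, B) arrays along the token axis
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

#' Add a positional embedding to a token sequence
#'
#' Elementwise addition of a learnable (N, C) table to every batch item; the
#' zero table is the identity.
#'
#' @param seq a [TokenSequence-class].
#' @param table an (N, C) matrix matching the sequence.
#' @return The shifted [TokenSequence-class].
#' @export
addPositionalEmbedding <- function(seq, table) {
  d <- dim(seq@tokens)
  if (nrow(table) != d[1] || ncol(table) != d[2])
    stop(sprintf("positional table %dx%d does not match sequence %dx%d",
                 nrow(table), ncol(table), d[1], d[2]))
  tokens <- seq@tokens + c(table)          # broadcasts over the batch axis
  tokenSequence(tokens, seq@grid, seq@hasClassToken)
}

#' ResNet-style residual block on a feature map
#'
#' `output = shortcut + conv2(GELU(conv1(input)))`; with all branch weights
#' zero the block is the identity map. When the branch output channel count
#' differs from the input, a 1x1 projection (`projW`, `projB`) must be
#' supplied for the shortcut and the output takes the branch's channel
#' count.
#'
#' @param x an (H, W, C) map or (H, W, C, B) batch.
#' @param W1,b1,W2,b2 branch convolution weights ((k, k, Cin, Cmid) etc.).
#' @param projW,projB optional 1x1 shortcut projection.
#' @return The residual-block output, same spatial shape.
#' @export
residualBlock <- function(x, W1, b1, W2, b2, projW = NULL, projB = NULL) {
  single <- length(dim(x)) == 3L
  if (single) x <- array(x, c(dim(x), 1L))
  pad1 <- (dim(W1)[1] - 1L) %/% 2L
  h <- convFwd(x, W1, b1, stride = 1L, pad = pad1)$out
  h <- geluActivation(h)
  pad2 <- (dim(W2)[1] - 1L) %/% 2L
  h <- convFwd(h, W2, b2, stride = 1L, pad = pad2)$out
  Cout <- dim(W2)[4]
  shortcut <- x
  if (Cout != dim(x)[3]) {
    if (is.null(projW))
      stop("channel mismatch between branch and shortcut: supply projW/projB")
    shortcut <- convFwd(x, projW, projB, stride = 1L, pad = 0L)$out
  }
  out <- shortcut + h
  if (single) out <- array(out, dim(out)[1:3])
  out
}
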