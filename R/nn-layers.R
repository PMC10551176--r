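# Neural-network primitives with explicit forward caches and hand-derived
# backward passes. Feature maps are (H, W, C, N) arrays; token batches are
# (Ntokens, C, B) arrays. Convolutions go through im2col + BLAS; depthwise
# convolution and max pooling are compiled kernels.

PADMODE <- c(zero = 0L, replicate = 1L)

# ---- standard convolution -------------------------------------------------

convFwd <- function(x, W, b, stride = 1L, pad = 1L, padmode = "replicate") {
  d <- dim(x); k <- dim(W)[1]
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], k, stride, pad,
                     PADMODE[[padmode]])
  Cout <- dim(W)[4]
  Wm <- matrix(W, ncol = Cout)
  Y <- cols %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1L
  out <- aperm(array(Y, c(Ho, Wo, d[4], Cout)), c(1, 2, 4, 3))
  list(out = out,
       cache = list(cols = cols, dims = d, k = k, stride = stride,
                    pad = pad, padmode = padmode))
}

convBwd <- function(cache, W, dout) {
  d <- dim(dout)                      # (Ho, Wo, Cout, N)
  Cout <- d[3]
  dYm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = Cout)
  dW <- array(crossprod(cache$cols, dYm), dim(W))
  db <- colSums(dYm)
  dcols <- tcrossprod(dYm, matrix(W, ncol = Cout))
  dims <- cache$dims
  dx <- array(col2im_cpp(dcols, dims[1], dims[2], dims[3], dims[4],
                         cache$k, cache$stride, cache$pad,
                         PADMODE[[cache$padmode]]), dims)
  list(dx = dx, dW = dW, db = db)
}

# ---- depthwise convolution (stride 1, "same" zero padding) ----------------

dwconvFwd <- function(x, K, b) {
  d <- dim(x); k <- dim(K)[1]
  out <- array(dwconv_fwd_cpp(x, d[1], d[2], d[3], d[4], K, k, b), d)
  list(out = out, cache = list(x = x, k = k))
}

dwconvBwd <- function(cache, K, dout) {
  d <- dim(cache$x)
  g <- dwconv_bwd_cpp(cache$x, K, dout, d[1], d[2], d[3], d[4], cache$k)
  list(dx = array(g$dx, d), dK = array(g$dK, dim(K)), db = g$db)
}

# ---- max pooling ----------------------------------------------------------

maxpoolFwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  r <- maxpool_fwd_cpp(x, d[1], d[2], d[3], d[4], k, stride, pad)
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1L
  list(out = array(r$out, c(Ho, Wo, d[3], d[4])),
       cache = list(argmax = r$argmax, inlen = length(x), dims = d))
}

maxpoolBwd <- function(cache, dout) {
  array(maxpool_bwd_cpp(dout, cache$argmax, cache$inlen), cache$dims)
}

# ---- GELU (exact, x * pnorm(x)) -------------------------------------------

#' Gaussian error linear unit
#'
#' The exact GELU, `x * pnorm(x)` with the standard normal CDF (not the tanh
#' approximation).
#'
#' @param x numeric vector/array.
#' @return `x * pnorm(x)`, same shape as `x`.
#' @examples
#' geluActivation(c(-1, 0, 1, 10))
#' @export
geluActivation <- function(x) x * stats::pnorm(x)

geluFwd <- function(x) {
  out <- x
  out[] <- gelu_fwd_cpp(x)
  list(out = out, cache = x)
}

geluBwd <- function(cache, dout) {
  out <- dout
  out[] <- gelu_bwd_cpp(cache, dout)
  out
}

# ---- batch normalization (per channel over H, W, N) -----------------------
# Biased (population) variance is used both in normalization and in the
# running moments, so the frozen statistics fold exactly into convolution
# weights at deployment.

bnFwd <- function(x, gamma, beta, runMean, runVar, training,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    runMean <- (1 - momentum) * runMean + momentum * mu
    runVar <- (1 - momentum) * runVar + momentum * va
  } else {
    mu <- runMean; va <- runVar
  }
  invstd <- 1 / sqrt(va + eps)
  n <- nrow(xm)
  xhat <- (xm - rep(mu, each = n)) * rep(invstd, each = n)
  ym <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  out <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(out = out, runMean = runMean, runVar = runVar,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    training = training))
}

bnBwd <- function(cache, dout) {
  d <- cache$d; C <- d[3]
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  n <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  gi <- rep(cache$gamma * cache$invstd, each = n)
  if (cache$training) {
    dxm <- gi * (dym - rep(dbeta / n, each = n) -
                   cache$xhat * rep(dgamma / n, each = n))
  } else {
    dxm <- gi * dym
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- layer normalization (per token over channels) ------------------------

lnFwd <- function(X, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(X)
  va <- rowMeans(X^2) - mu^2
  invstd <- 1 / sqrt(va + eps)
  xhat <- (X - mu) * invstd
  out <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(out = out, cache = list(xhat = xhat, invstd = invstd, gamma = gamma))
}

lnBwd <- function(cache, dout) {
  n <- nrow(dout); C <- ncol(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(cache$gamma, each = n)
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- linear ---------------------------------------------------------------

linearFwd <- function(X, W, b) {
  out <- X %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = X)
}

linearBwd <- function(cache, W, dout) {
  list(dx = tcrossprod(dout, W),      # dout %*% t(W)
       dW = crossprod(cache, dout), db = colSums(dout))
}

# ---- softmax utilities ----------------------------------------------------

softmaxRows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Cross-entropy over a (B, K) logit matrix with integer labels in 1..K.
# Returns mean loss and the gradient w.r.t. the logits.
softmaxCrossEntropy <- function(logits, labels) {
  p <- softmaxRows(logits)
  B <- nrow(logits)
  idx <- cbind(seq_len(B), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B)
}

# ---- token array <-> matrix reshapes --------------------------------------

tokToMat <- function(t3) {                 # (Nt, C, B) -> (Nt*B, C)
  d <- dim(t3)
  matrix(aperm(t3, c(1, 3, 2)), ncol = d[2])
}

matToTok <- function(m, Nt, B) {           # inverse of tokToMat
  aperm(array(m, c(Nt, B, ncol(m))), c(1, 3, 2))
}
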