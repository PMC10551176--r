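# Structural re-parameterization: fold each branch's normalization into its
# depthwise kernel, zero-pad all kernels to the largest size, add the
# identity branch as a centred Dirac kernel, and sum — one depthwise
# convolution plus bias that is mathematically equivalent (in inference
# mode) to the whole multi-branch mixer.

#' FusedMixerParams: a single-path token mixer
#'
#' The fused equivalent of a [MixerBlockParams-class]: one depthwise kernel
#' of the maximum branch size per channel, plus one bias per channel.
#'
#' @slot kernel (K, K, C) depthwise kernel.
#' @slot bias numeric(C).
#' @export
setClass("FusedMixerParams",
  representation(kernel = "array", bias = "numeric"),
  validity = function(object) {
    d <- dim(object@kernel)
    msg <- character()
    if (length(d) != 3L || d[1] != d[2]) msg <- c(msg, "kernel must be (K, K, C)")
    if (d[1] %% 2L == 0L) msg <- c(msg, "kernel size must be odd")
    if (length(object@bias) != d[3]) msg <- c(msg, "one bias per channel")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FusedMixerParams", function(object) {
  d <- dim(object@kernel)
  cat(sprintf("FusedMixerParams: %dx%d depthwise kernel, %d channels\n",
              d[1], d[2], d[3]))
})

#' Fold an inference-mode normalization into a depthwise kernel
#'
#' For y = gamma * (conv(x, kernel) - mu) / sqrt(var + eps) + beta, returns
#' kernel' = kernel * gamma / sqrt(var + eps) and
#' bias' = beta - mu * gamma / sqrt(var + eps), per channel, so that
#' conv(x, kernel') + bias' reproduces the normalized output exactly.
#'
#' @param kernel (k, k, C) depthwise kernel.
#' @param gamma,beta,mean,var per-channel normalization terms (length C).
#' @param eps variance floor; `var + eps` must be positive everywhere.
#' @return list(kernel, bias).
#' @examples
#' k <- array(1, c(3, 3, 1))
#' foldNorm(k, gamma = 1, beta = 0, mean = 0, var = 1, eps = 0)
#' @export
foldNorm <- function(kernel, gamma, beta, mean, var, eps = 1e-5) {
  if (any(var + eps <= 0))
    stop("non-positive variance + eps: cannot fold the normalization")
  C <- dim(kernel)[3]
  scale <- gamma / sqrt(var + eps)
  k2 <- kernel * rep(scale, each = dim(kernel)[1] * dim(kernel)[2])
  list(kernel = k2, bias = beta - mean * scale)
}

#' Centre-embed a small depthwise kernel in a larger one
#'
#' Zero-pads a (k, k, C) kernel into a (K, K, C) frame with the original
#' values centred; both sizes must be odd. The identity branch corresponds
#' to embedding the 1x1 Dirac kernel.
#'
#' @param kernel (k, k, C) array (a (k, k) matrix is treated as C = 1).
#' @param targetSize odd K >= k.
#' @return The (K, K, C) embedded kernel.
#' @examples
#' embedKernel(array(1, c(1, 1, 2)), 5)[3, 3, ]
#' @export
embedKernel <- function(kernel, targetSize) {
  if (is.matrix(kernel)) kernel <- array(kernel, c(dim(kernel), 1L))
  k <- dim(kernel)[1]; K <- as.integer(targetSize)
  if (k %% 2L == 0L || K %% 2L == 0L)
    stop("kernel sizes must be odd")
  if (K < k) stop("target size must be at least the kernel size")
  if (K == k) return(kernel)
  out <- array(0, c(K, K, dim(kernel)[3]))
  off <- (K - k) %/% 2L
  out[off + seq_len(k), off + seq_len(k), ] <- kernel
  out
}

diracKernel <- function(K, C) {
  out <- array(0, c(K, K, C))
  c0 <- (K + 1L) %/% 2L
  out[c0, c0, ] <- 1
  out
}

#' Fuse a multi-branch token mixer into a single depthwise convolution
#'
#' Sums, over branches, the normalization-folded kernels embedded to the
#' maximum branch size, plus a centred Dirac kernel for the identity branch;
#' biases add. The fused convolution reproduces the multi-branch mixer's
#' inference-mode output for every input (up to floating-point rounding).
#' Fusing an already-fused mixer is the identity.
#'
#' @param params a [MixerBlockParams-class] (or [FusedMixerParams-class],
#'   returned unchanged).
#' @return A [FusedMixerParams-class].
#' @export
setGeneric("fuseBlock", function(params) standardGeneric("fuseBlock"))

#' @rdname fuseBlock
#' @export
setMethod("fuseBlock", "MixerBlockParams", function(params) {
  validObject(params)
  K <- dim(params@kernels[[1]])[1]
  C <- dim(params@kernels[[1]])[3]
  kernel <- if (params@includeIdentity) diracKernel(K, C)
            else array(0, c(K, K, C))
  bias <- numeric(C)
  for (i in seq_along(params@kernels)) {
    f <- foldNorm(params@kernels[[i]], params@bn[[i]]$gamma,
                  params@bn[[i]]$beta, params@bn[[i]]$mean,
                  params@bn[[i]]$var, params@eps)
    kernel <- kernel + embedKernel(f$kernel, K)
    bias <- bias + f$bias
  }
  new("FusedMixerParams", kernel = kernel, bias = bias)
})

#' @rdname fuseBlock
#' @export
setMethod("fuseBlock", "FusedMixerParams", function(params) params)

# Assemble the MixerBlockParams of block l from a model's flat parameter /
# state lists.
blockParamsFromModel <- function(model, l) {
  cfg <- model@config@encoder
  kernels <- list(); bn <- list()
  for (i in seq_along(cfg$branchKernels)) {
    kernels[[i]] <- model@params[[sprintf("enc.b%d.mix.k%d", l, i)]]
    bn[[i]] <- list(gamma = model@params[[sprintf("enc.b%d.mix.g%d", l, i)]],
                    beta = model@params[[sprintf("enc.b%d.mix.b%d", l, i)]],
                    mean = model@state[[sprintf("enc.b%d.mix.rm%d", l, i)]],
                    var = model@state[[sprintf("enc.b%d.mix.rv%d", l, i)]])
  }
  mixerBlockParams(kernels, bn, cfg$includeIdentity, cfg$bnEps)
}

#' Freeze a model's normalization statistics
#'
#' Marks the batch-normalization running moments as final (inference mode).
#' Training does this automatically when it finishes; call it manually for
#' models assembled by hand before deploying them.
#'
#' @param model a [SmokeFormerModel-class].
#' @return The model with frozen statistics.
#' @export
freezeNorm <- function(model) {
  model@state$statsFrozen <- TRUE
  model
}

#' Deploy a trained model as a single-path inference network
#'
#' Replaces every multi-branch token mixer by its fused single depthwise
#' convolution ([fuseBlock()]); tokenizer, channel MLPs and head are already
#' single-path and stay unchanged. End-to-end logits agree with the training
#' topology to floating-point rounding, and the mixer layers carry strictly
#' fewer parameters. Deployment requires frozen normalization statistics and
#' refuses an already-deployed model.
#'
#' @param model a trained [SmokeFormerModel-class] in "train" topology.
#' @return The model in "deployed" topology.
#' @export
deployModel <- function(model) {
  if (model@topology == "deployed")
    stop("model is already deployed; refusing to re-fuse")
  if (!isTRUE(model@state$statsFrozen))
    stop("normalization statistics are not frozen; train the model or call freezeNorm() first")
  cfg <- model@config@encoder
  params <- model@params
  for (l in seq_len(cfg$depth)) {
    fused <- fuseBlock(blockParamsFromModel(model, l))
    drop <- c(mixerParamNames(l, length(cfg$branchKernels)))
    params[drop] <- NULL
    params[[sprintf("enc.b%d.fused.K", l)]] <- fused@kernel
    params[[sprintf("enc.b%d.fused.b", l)]] <- fused@bias
  }
  state <- model@state
  state[grep("^enc\\.", names(state))] <- NULL
  state$statsFrozen <- TRUE
  new("SmokeFormerModel", config = model@config, params = params,
      state = state, topology = "deployed")
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the weights, the full configuration, the normalization
#' state and the topology tag ("train" or "deployed"); `fuseCheckpoint`
#' converts a training checkpoint to a deployed one on disk and refuses a
#' checkpoint that is already fused.
#'
#' @param model a [SmokeFormerModel-class].
#' @param path checkpoint file path (RDS).
#' @return `loadCheckpoint` returns the model; the others the path,
#'   invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(format = "endosmoke-checkpoint", version = 1L,
               topology = model@topology, config = model@config,
               params = model@params, state = model@state), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "endosmoke-checkpoint"))
    stop("not an endosmoke checkpoint: ", path)
  new("SmokeFormerModel", config = ck$config, params = ck$params,
      state = ck$state, topology = ck$topology)
}

#' @rdname saveCheckpoint
#' @param outPath output path for the fused checkpoint.
#' @export
fuseCheckpoint <- function(path, outPath) {
  model <- loadCheckpoint(path)
  saveCheckpoint(deployModel(model), outPath)
  invisible(outPath)
}
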