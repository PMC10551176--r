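# Training protocol and evaluation: bilinear resize to the model input size,
# random horizontal-flip augmentation, AdamW with per-epoch exponential
# learning-rate decay, stratified k-fold cross-validation over the training
# split, and accuracy/sensitivity from the confusion counts with smoke as
# the positive class.

#' Read an image file
#'
#' PNG is read natively; other formats go through EBImage. Returns an
#' (H, W, 3) array on the [0, 255] scale (grayscale is replicated across
#' channels, an alpha channel is dropped).
#'
#' @param path image file path.
#' @return An (H, W, 3) array in [0, 255].
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Preprocess an image for the model
#'
#' Bilinear resize to the target size, rescale to [0, 1], and (in training
#' mode) random horizontal flip with the configured probability. The flip
#' draw uses the caller's RNG stream; pass `flip = TRUE/FALSE` to force it.
#'
#' @param image (H, W, 3) array, [0, 255] or [0, 1] scale.
#' @param size target (H, W) (a scalar is squared).
#' @param train training mode: enables the random flip.
#' @param flipProb horizontal-flip probability in training mode.
#' @param flip force (TRUE) or suppress (FALSE) the flip; NULL draws it.
#' @return An (H, W, 3) array in [0, 1].
#' @export
preprocessImage <- function(image, size, train = FALSE, flipProb = 0.5,
                            flip = NULL) {
  assertImage(image)
  if (length(size) == 1L) size <- rep(size, 2L)
  if (max(image) > 1) image <- image / 255
  if (any(dim(image)[1:2] != size))
    image <- EBImage::resize(image, w = size[1], h = size[2],
                             filter = "bilinear")
  if (is.null(flip)) flip <- train && stats::runif(1) < flipProb
  if (isTRUE(flip)) image <- image[, dim(image)[2]:1, , drop = FALSE]
  image
}

#' Exponentially decayed learning rate
#'
#' `lr = initialLR * decay^epoch` with `epoch` starting at 0.
#'
#' @param epoch 0-based epoch index.
#' @param initialLR initial learning rate (protocol default 0.001).
#' @param decay per-epoch decay factor in (0, 1].
#' @return The learning rate for that epoch.
#' @examples
#' exponentialLR(0)            # 0.001
#' exponentialLR(2, decay = 0.9)
#' @export
exponentialLR <- function(epoch, initialLR = 0.001, decay = 0.9) {
  if (epoch < 0) stop("epoch must be >= 0")
  initialLR * decay^epoch
}

#' Training configuration
#'
#' Defaults follow the full-scale protocol: 224 x 224 inputs, initial
#' learning rate 0.001 with exponential decay, 50 epochs, 10-fold
#' stratified cross-validation, random horizontal flips, encoder depth 10.
#' `tinyTrainConfig` is the small-scale protocol used by the test suite
#' (64 x 64, depth 2, width 64, 10 epochs).
#'
#' @param inputSize model input size after resizing.
#' @param initialLR,lrDecay exponential learning-rate schedule.
#' @param epochs training epochs.
#' @param folds cross-validation folds (>= 2).
#' @param flipProb horizontal-flip probability.
#' @param batchSize minibatch size.
#' @param weightDecay AdamW decoupled weight decay (weights only).
#' @param seed master seed for fold assignment, initialization, shuffling
#'   and augmentation.
#' @param model a [ModelConfig-class]; its inputSize must agree.
#' @return A validated list of training settings.
#' @export
trainConfig <- function(inputSize = 224L, initialLR = 0.001, lrDecay = 0.9,
                        epochs = 50L, folds = 10L, flipProb = 0.5,
                        batchSize = 32L, weightDecay = 0.01, seed = 1L,
                        model = modelConfig(
                          inputSize = inputSize,
                          tokenizer = tokenizerConfig(embedDim = 64L),
                          encoder = encoderConfig(depth = 10L,
                                                  embedDim = 64L))) {
  if (folds < 2L) stop("folds must be >= 2")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lrDecay <= 0 || lrDecay > 1) stop("decay factor must be in (0, 1]")
  if (any(model@inputSize != inputSize))
    stop("model inputSize does not match the training inputSize")
  list(inputSize = as.integer(inputSize), initialLR = initialLR,
       lrDecay = lrDecay, epochs = as.integer(epochs),
       folds = as.integer(folds), flipProb = flipProb,
       batchSize = as.integer(batchSize), weightDecay = weightDecay,
       seed = as.integer(seed), model = model)
}

#' @rdname trainConfig
#' @export
tinyTrainConfig <- function(seed = 1L, epochs = 10L, folds = 2L) {
  trainConfig(inputSize = 64L, epochs = epochs, folds = folds, seed = seed,
              model = modelConfig(inputSize = 64L,
                                  tokenizer = tokenizerConfig(embedDim = 64L),
                                  encoder = encoderConfig(depth = 2L,
                                                          embedDim = 64L)))
}

# ---- AdamW ----------------------------------------------------------------

decayedParam <- function(name) grepl("\\.(W[0-9]?|k[0-9]+)$", name)

adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamwStep <- function(params, grads, opt, lr, weightDecay = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1c <- 1 - beta1^opt$t; b2c <- 1 - beta2^opt$t
  for (n in names(grads)) {
    g <- grads[[n]]
    opt$m[[n]] <- beta1 * opt$m[[n]] + (1 - beta1) * g
    opt$v[[n]] <- beta2 * opt$v[[n]] + (1 - beta2) * g^2
    upd <- (opt$m[[n]] / b1c) / (sqrt(opt$v[[n]] / b2c) + eps)
    if (weightDecay > 0 && decayedParam(n)) upd <- upd + weightDecay * params[[n]]
    params[[n]] <- params[[n]] - lr * upd
  }
  list(params = params, opt = opt)
}

labelsToInt <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), CLASS_LEVELS)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  match(y, CLASS_LEVELS)
}

# ---- core fitting loop ----------------------------------------------------

#' Fit a model on an in-memory image array
#'
#' Minimizes the softmax cross-entropy with AdamW, per-epoch exponential
#' learning-rate decay and random horizontal flips. `x` must already be
#' resized to the model input size and scaled to [0, 1]
#' ([loadManifestImages()] produces this). Normalization statistics are
#' frozen when training finishes.
#'
#' @param model an initialized [SmokeFormerModel-class] in "train" topology.
#' @param x (H, W, 3, N) array in [0, 1].
#' @param y labels, "smoke" / "smoke_free", length N.
#' @param epochs,batchSize,initialLR,lrDecay,flipProb,weightDecay protocol
#'   settings (see [trainConfig()]).
#' @param seed seed for shuffling and augmentation.
#' @param verbose print the per-epoch mean loss.
#' @return list(model, log) where log is a data.frame(epoch, lr, loss).
#' @export
fitModel <- function(model, x, y, epochs = 10L, batchSize = 32L,
                     initialLR = 0.001, lrDecay = 0.9, flipProb = 0.5,
                     weightDecay = 0.01, seed = 1L, verbose = FALSE) {
  if (model@topology != "train")
    stop("a deployed model cannot be trained further")
  n <- dim(x)[4]
  if (n < batchSize)
    stop(sprintf("training set (%d) is smaller than the batch size (%d)",
                 n, batchSize))
  yi <- labelsToInt(y)
  params <- model@params; state <- model@state
  opt <- adamwInit(params)
  log <- data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      lr <- exponentialLR(ep - 1L, initialLR, lrDecay)
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        flips <- stats::runif(length(idx)) < flipProb
        if (any(flips))
          xb[, , , flips] <- xb[, dim(xb)[2]:1, , flips, drop = FALSE]
        work <- new("SmokeFormerModel", config = model@config,
                    params = params, state = state, topology = "train")
        fwd <- modelFwdFull(work, xb, training = TRUE)
        state <- fwd$state
        ce <- softmaxCrossEntropy(fwd$logits, yi[idx])
        losses <- c(losses, ce$loss)
        grads <- modelBwd(work, fwd$caches, ce$dlogits)
        stepped <- adamwStep(params, grads, opt, lr, weightDecay)
        params <- stepped$params; opt <- stepped$opt
      }
      log <- rbind(log, data.frame(epoch = ep, lr = lr,
                                   loss = mean(losses)))
      if (verbose)
        message(sprintf("epoch %d: lr %.5f loss %.4f", ep, lr, mean(losses)))
    }
  })
  state$statsFrozen <- TRUE
  list(model = new("SmokeFormerModel", config = model@config,
                   params = params, state = state, topology = "train"),
       log = log)
}

#' Load the images of a manifest split into memory
#'
#' @param manifest a [DatasetManifest-class].
#' @param split "train" or "test" (NULL for all).
#' @param size model input size; images are bilinearly resized.
#' @return list(x = (H, W, 3, N) array in [0, 1], y = label vector,
#'   paths = character).
#' @export
loadManifestImages <- function(manifest, split = NULL, size = 64L) {
  rec <- manifestRecords(manifest)
  if (!is.null(split)) rec <- rec[rec$split == split, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no images in the requested split")
  if (length(size) == 1L) size <- rep(size, 2L)
  x <- array(0, c(size[1], size[2], 3L, nrow(rec)))
  for (i in seq_len(nrow(rec)))
    x[, , , i] <- preprocessImage(
      readImageFile(file.path(manifest@dir, rec$path[i])), size)
  list(x = x, y = rec$label, paths = rec$path)
}

# Stratified fold assignment: within each label, shuffled indices are dealt
# round-robin over the folds, so each fold preserves the label ratio.
stratifiedFolds <- function(y, k, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (lv in unique(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  })
}

#' Train with stratified k-fold cross-validation
#'
#' Splits the manifest's training split into stratified folds; each fold
#' serves once as the validation set while a freshly initialized model is
#' trained on the rest (cross-entropy, AdamW, exponential learning-rate
#' decay, flip augmentation). Fold metrics report validation accuracy and
#' sensitivity. The returned final model is trained on the full training
#' split; cross-validation is used for selection/variance reporting only.
#'
#' @param cfg a [trainConfig()] list.
#' @param manifest a [DatasetManifest-class] with a train split.
#' @param outDir optional directory for per-fold and final checkpoints.
#' @param verbose print progress.
#' @return list(model, foldMetrics, foldAssignments, log).
#' @export
trainModel <- function(cfg, manifest, outDir = NULL, verbose = FALSE) {
  data <- loadManifestImages(manifest, "train", cfg$inputSize)
  n <- dim(data$x)[4]
  fold <- stratifiedFolds(data$y, cfg$folds, cfg$seed)
  if (min(table(fold)) < 1L || (n - max(table(fold))) < cfg$batchSize)
    stop("fold size too small for the configured batch size")
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  seeds <- deriveSeeds(cfg$seed, cfg$folds + 1L)
  foldMetrics <- data.frame()
  for (f in seq_len(cfg$folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    m0 <- initModel(cfg$model, seed = seeds[f])
    fit <- fitModel(m0, data$x[, , , tr, drop = FALSE], data$y[tr],
                    epochs = cfg$epochs, batchSize = cfg$batchSize,
                    initialLR = cfg$initialLR, lrDecay = cfg$lrDecay,
                    flipProb = cfg$flipProb, weightDecay = cfg$weightDecay,
                    seed = seeds[f], verbose = FALSE)
    foldRep <- evaluateArrays(fit$model, data$x[, , , va, drop = FALSE],
                              data$y[va])
    foldMetrics <- rbind(foldMetrics,
                         data.frame(fold = f, n = length(va),
                                    accuracy = reportAccuracy(foldRep),
                                    sensitivity = reportSensitivity(foldRep)))
    if (!is.null(outDir))
      saveCheckpoint(fit$model, file.path(outDir, sprintf("fold%02d.ckpt", f)))
    if (verbose)
      message(sprintf("fold %d/%d: acc %.3f sens %.3f", f, cfg$folds,
                      reportAccuracy(foldRep), reportSensitivity(foldRep)))
  }
  mF <- initModel(cfg$model, seed = seeds[cfg$folds + 1L])
  fit <- fitModel(mF, data$x, data$y, epochs = cfg$epochs,
                  batchSize = cfg$batchSize, initialLR = cfg$initialLR,
                  lrDecay = cfg$lrDecay, flipProb = cfg$flipProb,
                  weightDecay = cfg$weightDecay,
                  seed = seeds[cfg$folds + 1L], verbose = verbose)
  if (!is.null(outDir))
    saveCheckpoint(fit$model, file.path(outDir, "final.ckpt"))
  list(model = fit$model, foldMetrics = foldMetrics,
       foldAssignments = stats::setNames(fold, data$paths), log = fit$log)
}

# ---- evaluation -----------------------------------------------------------

#' Build a metrics report from confusion counts
#'
#' Acc = (TP+TN)/(TP+FN+FP+TN); Sens = TP/(TP+FN), reported as NaN with a
#' warning when no positive images were evaluated.
#'
#' @param tp,fp,fn,tn non-negative confusion counts (smoke = positive).
#' @param throughput optional images/second, informational.
#' @return A [MetricsReport-class].
#' @examples
#' confusionMetrics(3, 1, 1, 5)   # Acc 0.8, Sens 0.75
#' @export
confusionMetrics <- function(tp, fp, fn, tn, throughput = NA_real_) {
  counts <- c(TP = as.integer(tp), FP = as.integer(fp),
              FN = as.integer(fn), TN = as.integer(tn))
  acc <- (counts["TP"] + counts["TN"]) / sum(counts)
  sens <- if (counts["TP"] + counts["FN"] == 0L) {
    warning("no positive (smoke) images evaluated; sensitivity is undefined")
    NaN
  } else counts["TP"] / (counts["TP"] + counts["FN"])
  new("MetricsReport", accuracy = unname(acc), sensitivity = unname(sens),
      counts = counts, throughput = throughput)
}

# Evaluate on an in-memory array; used by CV and by evaluateModel.
evaluateArrays <- function(model, x, y, batchSize = 64L) {
  n <- dim(x)[4]
  pred <- character(n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    lg <- modelFwdFull(model, x[, , , idx, drop = FALSE],
                       training = FALSE)$logits
    pred[idx] <- CLASS_LEVELS[max.col(lg, ties.method = "first")]
  }
  confusionMetrics(tp = sum(pred == "smoke" & y == "smoke"),
                   fp = sum(pred == "smoke" & y == "smoke_free"),
                   fn = sum(pred == "smoke_free" & y == "smoke"),
                   tn = sum(pred == "smoke_free" & y == "smoke_free"))
}

#' Evaluate a model on a manifest split
#'
#' Accumulates the confusion counts with smoke as the positive class and
#' reports accuracy and sensitivity. The result is independent of image
#' order and batch size, and identical between the "train" and "deployed"
#' topologies of the same model.
#'
#' @param model a [SmokeFormerModel-class].
#' @param manifest a [DatasetManifest-class].
#' @param split which split to evaluate (default "test").
#' @param batchSize evaluation batch size.
#' @return A [MetricsReport-class].
#' @export
evaluateModel <- function(model, manifest, split = "test", batchSize = 64L) {
  data <- loadManifestImages(manifest, split, model@config@inputSize)
  evaluateArrays(model, data$x, data$y, batchSize)
}

#' Write a metrics report as JSON
#'
#' Emits {accuracy, sensitivity, tp, fp, fn, tn, throughput}.
#'
#' @param report a [MetricsReport-class].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeMetricsJSON <- function(report, path) {
  ct <- reportCounts(report)
  jsonlite::write_json(
    list(accuracy = report@accuracy, sensitivity = report@sensitivity,
         tp = unname(ct["TP"]), fp = unname(ct["FP"]),
         fn = unname(ct["FN"]), tn = unname(ct["TN"]),
         throughput = report@throughput),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Measure inference throughput
#'
#' Wall-clock images/second on random inputs at the model's input size,
#' median over `reps` repetitions after one warm-up pass. Informational
#' only: the number depends entirely on the host.
#'
#' @param model a [SmokeFormerModel-class].
#' @param nImages images per repetition (> 0).
#' @param batchSize forward batch size.
#' @param reps timed repetitions (the median is returned).
#' @param seed seed for the random inputs.
#' @return Median images/second.
#' @export
measureThroughput <- function(model, nImages = 32L, batchSize = 32L,
                              reps = 5L, seed = 1L) {
  if (nImages < 1L) stop("nImages must be positive")
  sz <- model@config@inputSize
  x <- withSeed(seed, array(stats::runif(sz[1] * sz[2] * 3 * nImages),
                            c(sz[1], sz[2], 3L, nImages)))
  runOnce <- function() {
    for (start in seq(1L, nImages, by = batchSize)) {
      idx <- start:min(start + batchSize - 1L, nImages)
      modelFwdFull(model, x[, , , idx, drop = FALSE], training = FALSE)
    }
  }
  runOnce()                                  # warm-up, excluded
  times <- vapply(seq_len(reps), function(i) {
    t0 <- proc.time()[["elapsed"]]; runOnce()
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  nImages / stats::median(times)
}
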