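# S4 classes shared across the package.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' SmokeParams: parameters of one rendered smoke layer
#'
#' The triple (intensity, density, position) controls one translucent smoke
#' plume: intensity scales the peak added luminance, density the spatial
#' extent of the plume, and position its centre in 0-based (row, col) pixel
#' coordinates. A seed makes the fractal noise field reproducible.
#'
#' @slot intensity numeric in [0, 1].
#' @slot density numeric in [0, 1].
#' @slot position numeric(2), 0-based (row, col) plume centre.
#' @slot seed integer RNG seed for the noise field.
#' @export
setClass("SmokeParams",
  representation(intensity = "numeric", density = "numeric",
                 position = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@intensity < 0 || object@intensity > 1)
      msg <- c(msg, "intensity must lie in [0, 1]")
    if (object@density < 0 || object@density > 1)
      msg <- c(msg, "density must lie in [0, 1]")
    if (length(object@position) != 2L || any(!is.finite(object@position)))
      msg <- c(msg, "position must be a finite (row, col) pair")
    if (length(msg)) msg else TRUE
  })

#' Construct smoke-plume parameters
#'
#' @param intensity peak-luminance scale in [0, 1]; 0 renders no smoke.
#' @param density spatial-extent scale in [0, 1]; larger plumes cover more
#'   of the frame.
#' @param position 0-based (row, col) centre of the plume, inside the frame.
#' @param seed integer seed for the plume's noise field.
#' @return A [SmokeParams-class] object.
#' @examples
#' smokeParams(0.8, 0.5, c(96, 192), seed = 7L)
#' @export
smokeParams <- function(intensity, density, position, seed = 1L) {
  new("SmokeParams", intensity = as.numeric(intensity),
      density = as.numeric(density), position = as.numeric(position),
      seed = as.integer(seed))
}

setMethod("show", "SmokeParams", function(object) {
  cat(sprintf("SmokeParams: intensity=%.3f density=%.3f centre=(%g, %g) seed=%d\n",
              object@intensity, object@density, object@position[1],
              object@position[2], object@seed))
})

#' SmokeLayer: one rendered additive smoke field
#'
#' Non-negative additive luminance contributions on the frame grid, plus the
#' boolean support mask marking pixels with a nonzero contribution. Values
#' are zero exactly where the mask is FALSE.
#'
#' @slot values numeric H x W matrix of additive luminance (0-255 scale).
#' @slot mask logical H x W support mask.
#' @export
setClass("SmokeLayer",
  representation(values = "matrix", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@values) == dim(object@mask)))
      msg <- c(msg, "values and mask dimensions differ")
    if (any(object@values < 0))
      msg <- c(msg, "smoke values must be non-negative")
    if (any((object@values == 0) != !object@mask))
      msg <- c(msg, "mask must be TRUE exactly where values are nonzero")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SmokeLayer", function(object) {
  cat(sprintf("SmokeLayer: %d x %d, support %.1f%%, peak %.1f\n",
              nrow(object@values), ncol(object@values),
              100 * mean(object@mask), max(object@values)))
})

#' @describeIn smokeSupportFraction Peak added luminance of a layer.
#' @export
smokePeak <- function(layer) max(layer@values)

#' Support fraction and peak of a smoke layer
#'
#' @param layer a [SmokeLayer-class].
#' @return Fraction of frame pixels with nonzero contribution (or the peak
#'   value, for `smokePeak`).
#' @export
smokeSupportFraction <- function(layer) mean(layer@mask)

#' DatasetManifest: a built synthetic dataset
#'
#' Records one (path, label, split) row per written image, the master seed,
#' and the per-(label, split) tally.
#'
#' @slot records data.frame with columns path, label, split.
#' @slot seed integer master seed of the build.
#' @slot counts data.frame tally with columns label, split, n.
#' @slot dir character root directory the paths are relative to.
#' @export
setClass("DatasetManifest",
  representation(records = "data.frame", seed = "integer",
                 counts = "data.frame", dir = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("path", "label", "split")
    if (!all(need %in% names(object@records)))
      msg <- c(msg, "records must have columns path, label, split")
    if (anyDuplicated(object@records$path))
      msg <- c(msg, "duplicate image paths in manifest")
    if (!all(object@records$label %in% c("smoke", "smoke_free")))
      msg <- c(msg, "labels must be 'smoke' or 'smoke_free'")
    if (!all(object@records$split %in% c("train", "test")))
      msg <- c(msg, "splits must be 'train' or 'test'")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "DatasetManifest", function(object) {
  cat("DatasetManifest:", nrow(object@records), "images (seed",
      object@seed, ")\n")
  print(manifestCounts(object))
})

#' Manifest accessors
#'
#' @param manifest a [DatasetManifest-class].
#' @return `manifestRecords` returns the records data.frame,
#'   `manifestCounts` a label x split contingency table.
#' @export
manifestRecords <- function(manifest) manifest@records

#' @rdname manifestRecords
#' @export
manifestCounts <- function(manifest) {
  with(manifest@records, table(label = label, split = split))
}

#' TokenSequence: a batch of token sequences with grid metadata
#'
#' Tokens are stored as an (N tokens, C channels, B batch) array. The spatial
#' grid (Hg, Wg) satisfies Hg*Wg = N, or N - 1 when a class token is
#' prepended (the class token occupies index 1 and is carried alongside the
#' grid during spatial mixing).
#'
#' @slot tokens numeric array (N, C, B).
#' @slot grid integer(2) spatial grid (Hg, Wg).
#' @slot hasClassToken logical.
#' @export
setClass("TokenSequence",
  representation(tokens = "array", grid = "integer",
                 hasClassToken = "logical"),
  validity = function(object) {
    d <- dim(object@tokens)
    msg <- character()
    if (length(d) != 3L) msg <- c(msg, "tokens must be an (N, C, B) array")
    nGrid <- prod(object@grid)
    expected <- nGrid + as.integer(object@hasClassToken)
    if (length(d) == 3L && d[1] != expected)
      msg <- c(msg, sprintf("token count %d inconsistent with grid %dx%d (class token: %s)",
                            d[1], object@grid[1], object@grid[2],
                            object@hasClassToken))
    if (length(d) == 3L && d[1] < 1L) msg <- c(msg, "need at least one token")
    if (length(msg)) msg else TRUE
  })

#' Construct a token sequence
#'
#' @param tokens (N, C) matrix or (N, C, B) array.
#' @param grid integer(2) spatial grid dimensions.
#' @param hasClassToken whether token 1 is a class token outside the grid.
#' @return A [TokenSequence-class].
#' @export
tokenSequence <- function(tokens, grid, hasClassToken = FALSE) {
  if (length(dim(tokens)) == 2L)
    tokens <- array(tokens, c(dim(tokens), 1L))
  new("TokenSequence", tokens = tokens, grid = as.integer(grid),
      hasClassToken = hasClassToken)
}

setMethod("show", "TokenSequence", function(object) {
  d <- dim(object@tokens)
  cat(sprintf("TokenSequence: %d tokens x %d channels x %d batch, grid %dx%d%s\n",
              d[1], d[2], d[3], object@grid[1], object@grid[2],
              if (object@hasClassToken) " (+class token)" else ""))
})

#' Token-sequence accessors
#'
#' @param seq a [TokenSequence-class].
#' @param batch batch index for `tokenMatrix`.
#' @return Number of tokens, embedding dim, the (N, C) matrix of one batch
#'   item, or the grid.
#' @export
nTokens <- function(seq) dim(seq@tokens)[1]

#' @rdname nTokens
#' @export
embedDim <- function(seq) dim(seq@tokens)[2]

#' @rdname nTokens
#' @export
tokenGrid <- function(seq) seq@grid

#' @rdname nTokens
#' @export
tokenMatrix <- function(seq, batch = 1L) seq@tokens[, , batch]

#' Model configuration
#'
#' Aggregates tokenizer, encoder and head hyper-parameters together with the
#' (single, fixed) input size of the trained model.
#'
#' @slot inputSize integer(2) (H, W) the model expects after preprocessing.
#' @slot tokenizer list of tokenizer settings (see [tokenizerConfig()]).
#' @slot encoder list of encoder settings (see [encoderConfig()]).
#' @slot nClasses integer, 2 for smoke vs smoke-free.
#' @slot hiddenHead logical; optional one-hidden-layer MLP head instead of
#'   the default single linear classifier.
#' @export
setClass("ModelConfig",
  representation(inputSize = "integer", tokenizer = "list",
                 encoder = "list", nClasses = "integer",
                 hiddenHead = "logical"))

#' SmokeFormerModel: the classifier with its weights
#'
#' @slot config a [ModelConfig-class].
#' @slot params named flat list of parameter arrays.
#' @slot state named flat list of non-trained state (batch-norm running
#'   moments, `statsFrozen` flag).
#' @slot topology "train" (multi-branch mixers) or "deployed" (fused
#'   single-path mixers).
#' @export
setClass("SmokeFormerModel",
  representation(config = "ModelConfig", params = "list", state = "list",
                 topology = "character"),
  validity = function(object) {
    if (!object@topology %in% c("train", "deployed"))
      "topology must be 'train' or 'deployed'" else TRUE
  })

setMethod("show", "SmokeFormerModel", function(object) {
  cfg <- object@config
  cat(sprintf("SmokeFormerModel (%s topology)\n", object@topology))
  cat(sprintf("  input %dx%d, stride %d, embed dim %d, depth %d\n",
              cfg@inputSize[1], cfg@inputSize[2],
              cfg@tokenizer$totalStride, cfg@tokenizer$embedDim,
              cfg@encoder$depth))
  cat(sprintf("  parameters: %d\n", nParameters(object)))
})

#' Number of trainable parameters
#'
#' @param model a [SmokeFormerModel-class].
#' @param pattern optional regular expression restricting to matching
#'   parameter names (e.g. `"mixer"` for token-mixer parameters only).
#' @return Integer parameter count.
#' @export
nParameters <- function(model, pattern = NULL) {
  p <- model@params
  if (!is.null(pattern)) p <- p[grepl(pattern, names(p))]
  sum(vapply(p, length, integer(1)))
}

#' @rdname nParameters
#' @export
modelTopology <- function(model) model@topology

#' Prediction for one image
#'
#' @slot logits named numeric(2) raw class scores.
#' @slot label predicted class, "smoke" or "smoke_free".
#' @slot score softmax probability of the predicted class.
#' @export
setClass("Prediction",
  representation(logits = "numeric", label = "character", score = "numeric"),
  validity = function(object) {
    p <- exp(object@logits - max(object@logits))
    p <- p / sum(p)
    msg <- character()
    if (abs(sum(p) - 1) > 1e-6) msg <- c(msg, "softmax must sum to 1")
    if (names(object@logits)[which.max(object@logits)] != object@label)
      msg <- c(msg, "label must be the argmax of the logits")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Prediction", function(object) {
  cat(sprintf("Prediction: %s (p = %.4f)\n", object@label, object@score))
})

#' MetricsReport: evaluation summary
#'
#' Accuracy and sensitivity derived from the confusion counts with smoke as
#' the positive class: Acc = (TP+TN)/(TP+FN+FP+TN), Sens = TP/(TP+FN).
#'
#' @slot accuracy numeric in [0, 1].
#' @slot sensitivity numeric in [0, 1] (NaN when no positives were evaluated).
#' @slot counts named integer(4): TP, FP, FN, TN.
#' @slot throughput numeric images/second, informational only (NA when not
#'   measured).
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 counts = "integer", throughput = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(c("TP", "FP", "FN", "TN") %in% names(object@counts)))
      msg <- c(msg, "counts must be named TP, FP, FN, TN")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "MetricsReport", function(object) {
  ct <- object@counts
  cat(sprintf("MetricsReport: Acc %.4f, Sens %s on %d images\n",
              object@accuracy,
              ifelse(is.nan(object@sensitivity), "NaN",
                     sprintf("%.4f", object@sensitivity)),
              sum(ct)))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d", ct["TP"], ct["FP"],
              ct["FN"], ct["TN"]))
  if (!is.na(object@throughput))
    cat(sprintf("  (%.1f images/s)", object@throughput))
  cat("\n")
})

#' Metrics accessors
#'
#' @param report a [MetricsReport-class].
#' @return The accuracy, sensitivity, or named confusion counts.
#' @export
reportAccuracy <- function(report) report@accuracy

#' @rdname reportAccuracy
#' @export
reportSensitivity <- function(report) report@sensitivity

#' @rdname reportAccuracy
#' @export
reportCounts <- function(report) report@counts
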