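# Procedural generator of endoscopic-style frames and additive smoke plumes.
#
# Images are plain (H, W, 3) base-R arrays with intensities on the [0, 255]
# scale (0-based (row, col) coordinates, origin top-left). The generator
# emulates the statistical character of laparoscopic frames — low-texture,
# red-dominant tissue under a vignetting light cone with sparse specular
# highlights — and composites translucent smoke additively, pixel by pixel:
# smoky = clean + smoke, clipped at sensor saturation.

# Multi-octave value noise in [0, 1]: coarse random lattices upsampled
# bilinearly and summed with geometrically decaying weights.
valueNoise <- function(height, width, octaves = 4L, baseCells = 4L) {
  acc <- matrix(0, height, width)
  wsum <- 0
  for (o in seq_len(octaves)) {
    cells <- baseCells * 2L^(o - 1L)
    g <- matrix(runif((cells + 1L)^2), cells + 1L, cells + 1L)
    w <- 0.5^(o - 1L)
    acc <- acc + w * EBImage::resize(g, w = height, h = width,
                                     filter = "bilinear")
    wsum <- wsum + w
  }
  acc / wsum
}

assertImage <- function(img, what = "image") {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L))
    stop(what, " must be an (H, W, 3) array")
  invisible(img)
}

#' Generate a synthetic smoke-free endoscopic-style frame
#'
#' Produces a deterministic, low-texture, red-dominant frame emulating
#' non-Lambertian tissue: multi-octave smooth value noise drives the red and
#' green channels, a radial vignette darkens the periphery of the light cone,
#' and 0-3 specular highlight blobs mimic wet-surface reflections.
#'
#' @param seed integer; the frame is a pure function of the seed.
#' @param height,width frame dimensions in pixels, both >= 32.
#' @return An (H, W, 3) array with values in [0, 255]; the red channel mean
#'   always exceeds the blue channel mean.
#' @examples
#' frame <- generateBaseFrame(1L, 64, 96)
#' mean(frame[, , 1]) > mean(frame[, , 3])
#' @export
generateBaseFrame <- function(seed, height, width) {
  if (height < 32 || width < 32)
    stop("invalid dimensions: height and width must both be >= 32")
  withSeed(seed, {
    nR <- valueNoise(height, width)
    nG <- valueNoise(height, width)
    red   <- 0.52 + 0.26 * nR
    green <- 0.20 + 0.16 * nG
    blue  <- 0.10 + 0.07 * nG

    # radial vignette: normalized squared distance from the optical centre
    ry <- ((seq_len(height) - 0.5) / height - 0.5) * 2
    rx <- ((seq_len(width) - 0.5) / width - 0.5) * 2
    d2 <- outer(ry^2, rx^2, `+`)
    vig <- 1 - 0.25 * d2

    img <- array(0, c(height, width, 3L))
    img[, , 1] <- red * vig
    img[, , 2] <- green * vig
    img[, , 3] <- blue * vig

    nHi <- sample(0:3, 1L)
    if (nHi > 0) {
      for (i in seq_len(nHi)) {
        cy <- runif(1, 0.15, 0.85) * height
        cx <- runif(1, 0.15, 0.85) * width
        sg <- runif(1, 0.01, 0.04) * min(height, width)
        amp <- runif(1, 0.25, 0.6)
        blob <- amp * exp(-0.5 * outer((seq_len(height) - cy)^2,
                                       (seq_len(width) - cx)^2, `+`) / sg^2)
        for (ch in 1:3) img[, , ch] <- img[, , ch] + blob
      }
    }
    255 * pmin(pmax(img, 0), 1)
  })
}

#' Render a procedural smoke plume
#'
#' A translucent smoke layer is a multi-octave fractal noise field modulated
#' by a smooth elliptical-Gaussian envelope centred at `params@position`.
#' Intensity scales the peak added luminance; density scales the spatial
#' extent of the plume (the envelope is truncated below a small cutoff so the
#' layer has finite support and exact zeros outside it).
#'
#' @param params a [SmokeParams-class]; `intensity = 0` yields an empty layer.
#' @param height,width frame dimensions in pixels.
#' @return A [SmokeLayer-class] whose peak value is strictly monotone in
#'   intensity and whose support fraction is monotone in density.
#' @examples
#' sl <- renderSmoke(smokeParams(0.8, 0.5, c(32, 48), seed = 3L), 64, 96)
#' smokePeak(sl); smokeSupportFraction(sl)
#' @export
renderSmoke <- function(params, height, width) {
  validObject(params)
  pos <- params@position
  if (pos[1] < 0 || pos[1] > height - 1 || pos[2] < 0 || pos[2] > width - 1)
    stop("smoke position lies outside the frame bounds")
  if (params@intensity == 0) {
    z <- matrix(0, height, width)
    return(new("SmokeLayer", values = z, mask = z > 0))
  }
  withSeed(params@seed, {
    noise <- valueNoise(height, width)
    # support radii grow linearly with density, staying below the frame size
    Rr <- (0.08 + 0.42 * params@density) * height
    Rc <- (0.08 + 0.42 * params@density) * width
    cut <- 0.05
    sr <- Rr / sqrt(-2 * log(cut))
    sc <- Rc / sqrt(-2 * log(cut))
    dr <- (seq_len(height) - 1 - pos[1]) / sr
    dc <- (seq_len(width) - 1 - pos[2]) / sc
    env <- exp(-0.5 * outer(dr^2, dc^2, `+`))
    env[env < cut] <- 0
    vals <- 255 * params@intensity * env * (0.35 + 0.65 * noise)
    new("SmokeLayer", values = vals, mask = vals > 0)
  })
}

#' Composite a smoke layer onto a clean frame
#'
#' Pure per-pixel, per-channel addition of the smoke luminance (the same
#' scalar field added to R, G and B), clipped at sensor saturation (255).
#' Pixels outside the smoke support are bit-identical to the original.
#'
#' @param original an (H, W, 3) array in [0, 255].
#' @param smoke a [SmokeLayer-class] with matching spatial dimensions.
#' @return The composited (H, W, 3) array.
#' @examples
#' img <- generateBaseFrame(1L, 64, 64)
#' sl <- renderSmoke(smokeParams(0.7, 0.5, c(32, 32)), 64, 64)
#' smoky <- composeSmoke(img, sl)
#' all(smoky >= img)
#' @export
composeSmoke <- function(original, smoke) {
  assertImage(original, "original")
  d <- dim(original)
  if (d[1] != nrow(smoke@values) || d[2] != ncol(smoke@values))
    stop("image and smoke layer dimensions do not match")
  out <- original
  for (ch in 1:3) out[, , ch] <- pmin(original[, , ch] + smoke@values, 255)
  out
}

#' Dataset-build configuration
#'
#' `smokeDatasetConfig` assembles the settings of one synthetic dataset
#' build; `fullScaleConfig` is the full-scale preset (5,000 frames of
#' 384 x 192, one fifth smoke-composited, 3,800 train / 1,200 test, a 4:1
#' smoke-free:smoke ratio in each split); `reducedScaleConfig` is a small
#' preset used throughout the test suite. All cell counts
#' (label x split) must come out integer, otherwise [buildSmokeDataset()]
#' refuses the configuration.
#'
#' @param total number of images.
#' @param smokeFraction fraction of images that receive smoke (default 1/5,
#'   i.e. a 4:1 smoke-free:smoke ratio).
#' @param testFraction fraction of images (within each label, stratified)
#'   held out as the test split.
#' @param height,width frame size in pixels.
#' @param intensityRange,densityRange uniform sampling ranges of the smoke
#'   parameters; the defaults keep every smoke-labeled frame visibly smoky.
#' @return A named list of settings.
#' @export
smokeDatasetConfig <- function(total, smokeFraction = 0.2,
                               testFraction = 0.24,
                               height = 192L, width = 384L,
                               intensityRange = c(0.3, 1.0),
                               densityRange = c(0.3, 0.9)) {
  list(total = as.integer(total), smokeFraction = smokeFraction,
       testFraction = testFraction, height = as.integer(height),
       width = as.integer(width), intensityRange = intensityRange,
       densityRange = densityRange)
}

#' @rdname smokeDatasetConfig
#' @export
fullScaleConfig <- function() smokeDatasetConfig(5000L)

#' @rdname smokeDatasetConfig
#' @export
reducedScaleConfig <- function(total = 50L, height = 64L, width = 64L) {
  smokeDatasetConfig(total, testFraction = 0.2, height = height,
                     width = width)
}

#' Read a dataset-build configuration from a YAML file
#'
#' Recognized fields: total, smoke_fraction, test_fraction, height, width,
#' intensity_range, density_range. Missing fields fall back to the
#' [smokeDatasetConfig()] defaults.
#'
#' @param path YAML file path.
#' @return A config list as from [smokeDatasetConfig()].
#' @export
readDatasetConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- smokeDatasetConfig(y$total)
  map <- c(smoke_fraction = "smokeFraction", test_fraction = "testFraction",
           height = "height", width = "width",
           intensity_range = "intensityRange",
           density_range = "densityRange")
  for (k in names(map))
    if (!is.null(y[[k]])) cfg[[map[[k]]]] <- y[[k]]
  cfg$height <- as.integer(cfg$height); cfg$width <- as.integer(cfg$width)
  cfg
}

datasetCells <- function(config) {
  tol <- 1e-9
  nSmoke <- config$total * config$smokeFraction
  cells <- c(smokeTest = nSmoke * config$testFraction,
             freeTest = (config$total - nSmoke) * config$testFraction)
  whole <- function(x) abs(x - round(x)) < tol
  if (!whole(nSmoke) || !all(whole(cells)))
    stop(sprintf(paste0(
      "configuration does not yield integer per-(label, split) counts: ",
      "total=%d, smoke fraction=%g, test fraction=%g give smoke=%g, ",
      "smoke/test=%g, smoke-free/test=%g; choose a total divisible by the ",
      "fraction denominators"),
      config$total, config$smokeFraction, config$testFraction, nSmoke,
      cells["smokeTest"], cells["freeTest"]))
  nSmoke <- as.integer(round(nSmoke))
  list(nSmoke = nSmoke, nFree = config$total - nSmoke,
       smokeTest = as.integer(round(cells["smokeTest"])),
       freeTest = as.integer(round(cells["freeTest"])))
}

#' Build a labeled synthetic smoke / smoke-free dataset
#'
#' Writes `config$total` PNG frames under `file.path(outDir, "images")` plus
#' a `manifest.csv` (header `path,label,split`, paths relative to `outDir`).
#' Labels and the stratified train/test assignment are drawn once from the
#' master seed; each smoke frame receives intensity and density drawn
#' uniformly from the configured ranges and a plume centre uniform over the
#' central region of the frame. The build is byte-for-byte reproducible from
#' (config, seed).
#'
#' @param config a list from [smokeDatasetConfig()] or [fullScaleConfig()].
#' @param outDir output directory (created if missing).
#' @param seed master integer seed.
#' @param verbose print a progress line every 500 images.
#' @return A [DatasetManifest-class].
#' @examples
#' \donttest{
#' md <- buildSmokeDataset(reducedScaleConfig(25L), tempfile(), seed = 1L)
#' manifestCounts(md)
#' }
#' @export
buildSmokeDataset <- function(config, outDir, seed = 1L, verbose = FALSE) {
  cells <- datasetCells(config)
  total <- config$total
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)

  plan <- withSeed(seed, {
    label <- rep("smoke_free", total)
    label[sample.int(total, cells$nSmoke)] <- "smoke"
    split <- rep("train", total)
    smokeIdx <- which(label == "smoke")
    freeIdx <- which(label == "smoke_free")
    split[sample(smokeIdx, cells$smokeTest)] <- "test"
    split[sample(freeIdx, cells$freeTest)] <- "test"
    data.frame(
      path = sprintf("images/img_%05d.png", seq_len(total)),
      label = label, split = split,
      intensity = runif(total, config$intensityRange[1],
                        config$intensityRange[2]),
      density = runif(total, config$densityRange[1], config$densityRange[2]),
      posRow = runif(total, 0.2, 0.8) * (config$height - 1),
      posCol = runif(total, 0.2, 0.8) * (config$width - 1),
      imgSeed = sample.int(2147483000L, total),
      stringsAsFactors = FALSE)
  })

  for (i in seq_len(total)) {
    img <- generateBaseFrame(plan$imgSeed[i], config$height, config$width)
    if (plan$label[i] == "smoke") {
      sp <- smokeParams(plan$intensity[i], plan$density[i],
                        c(plan$posRow[i], plan$posCol[i]),
                        seed = plan$imgSeed[i] + 1L)
      img <- composeSmoke(img, renderSmoke(sp, config$height, config$width))
    }
    png::writePNG(img / 255, file.path(outDir, plan$path[i]))
    if (verbose && i %% 500L == 0L)
      message(sprintf("  wrote %d / %d images", i, total))
  }

  records <- plan[, c("path", "label", "split")]
  stopifnot(all(file.exists(file.path(outDir, records$path))))
  utils::write.table(records, file.path(outDir, "manifest.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  counts <- as.data.frame(table(label = records$label,
                                split = records$split),
                          responseName = "n")
  new("DatasetManifest", records = records, seed = as.integer(seed),
      counts = counts, dir = normalizePath(outDir))
}

#' Read a dataset manifest from disk
#'
#' @param path the manifest CSV (or the dataset directory containing
#'   `manifest.csv`).
#' @return A [DatasetManifest-class]; the seed slot is NA for a manifest
#'   read back from disk.
#' @export
readManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts <- as.data.frame(table(label = records$label,
                                split = records$split),
                          responseName = "n")
  new("DatasetManifest", records = records, seed = NA_integer_,
      counts = counts, dir = normalizePath(dirname(path)))
}
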