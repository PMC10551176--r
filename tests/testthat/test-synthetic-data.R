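# Synthetic frame generation, smoke rendering and dataset construction.

test_that("base frames are deterministic, seed-sensitive and red-dominant", {
  f1 <- generateBaseFrame(1L, 64, 96)
  f2 <- generateBaseFrame(1L, 64, 96)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(64L, 96L, 3L))
  expect_true(all(f1 >= 0 & f1 <= 255))

  g <- generateBaseFrame(2L, 64, 96)
  expect_gt(mean(f1 != g), 0.01)

  for (s in 1:20) {
    fr <- generateBaseFrame(s, 48, 48)
    expect_gt(mean(fr[, , 1]), mean(fr[, , 3]))
  }
})

test_that("frame generation rejects degenerate dimensions", {
  expect_error(generateBaseFrame(1L, 16, 64), "dimensions")
  expect_error(generateBaseFrame(1L, 64, 8), "dimensions")
})

test_that("smoke layers honor the intensity/density contracts", {
  expect_identical(smokePeak(renderSmoke(smokeParams(0, 0.5, c(32, 32)),
                                         64, 64)), 0)

  peaks <- vapply(seq(0.2, 1.0, length.out = 5), function(tint)
    smokePeak(renderSmoke(smokeParams(tint, 0.5, c(32, 32), seed = 7L),
                          64, 64)), numeric(1))
  expect_true(all(diff(peaks) > 0))

  supp <- vapply(seq(0.2, 0.8, length.out = 5), function(dens)
    smokeSupportFraction(renderSmoke(smokeParams(0.8, dens, c(32, 32),
                                                 seed = 7L), 64, 64)),
    numeric(1))
  expect_true(all(diff(supp) > 0))

  sl <- renderSmoke(smokeParams(0.8, 0.5, c(32, 32), seed = 3L), 64, 64)
  expect_true(all(sl@values >= 0))
  expect_identical(sl@values > 0, sl@mask)
  expect_identical(sl@values,
                   renderSmoke(smokeParams(0.8, 0.5, c(32, 32), seed = 3L),
                               64, 64)@values)
  expect_error(renderSmoke(smokeParams(0.5, 0.5, c(200, 10)), 64, 64),
               "outside")
  expect_error(smokeParams(1.4, 0.5, c(10, 10)))
})

test_that("compositing is additive, clipped, and exact outside the support", {
  img <- generateBaseFrame(5L, 32, 32)
  zero <- new("SmokeLayer", values = matrix(0, 32, 32),
              mask = matrix(FALSE, 32, 32))
  expect_identical(composeSmoke(img, zero), img)

  img[1, 1, ] <- c(200, 180, 170)
  img[2, 2, ] <- c(10, 10, 10)
  vals <- matrix(0, 32, 32); vals[1, 1] <- 90; vals[2, 2] <- 40
  sl <- new("SmokeLayer", values = vals, mask = vals > 0)
  out <- composeSmoke(img, sl)
  expect_equal(out[1, 1, ], c(255, 255, 255))
  expect_equal(out[2, 2, ], c(50, 50, 50))
  expect_true(all(out >= img))
  expect_identical(out[vals == 0], img[vals == 0])

  expect_error(composeSmoke(img, renderSmoke(smokeParams(0.5, 0.5, c(5, 5)),
                                             48, 48)), "match")
})

test_that("smoke-composited frames are brighter than their base frames", {
  for (s in 1:5) {
    base <- generateBaseFrame(s, 48, 48)
    sl <- renderSmoke(smokeParams(runif(1, 0.3, 1), runif(1, 0.3, 0.9),
                                  c(24, 24), seed = s), 48, 48)
    expect_gt(mean(composeSmoke(base, sl)), mean(base))
  }
})

test_that("dataset builds hit the configured counts and exact split ratios", {
  md <- sharedTinyDataset()
  ct <- manifestCounts(md)
  expect_equal(sum(ct), 50)
  expect_equal(sum(ct["smoke", ]), 10)
  expect_equal(unname(ct[, "train"]), c(8, 32))   # smoke, smoke_free
  expect_equal(unname(ct[, "test"]), c(2, 8))
  for (sp in c("train", "test"))
    expect_equal(ct["smoke_free", sp] / ct["smoke", sp], 4)

  rec <- manifestRecords(md)
  expect_false(anyDuplicated(rec$path) > 0)
  expect_true(all(file.exists(file.path(md@dir, rec$path))))
})

test_that("configurations with non-integer label-split cells are rejected", {
  expect_error(buildSmokeDataset(smokeDatasetConfig(50L, testFraction = 0.24),
                                 tempfile(), seed = 1L), "integer")
})

test_that("dataset builds are byte-for-byte reproducible from the seed", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- reducedScaleConfig(total = 25L, height = 48L, width = 48L)
  cfg$testFraction <- 0.2
  buildSmokeDataset(cfg, d1, seed = 9L)
  buildSmokeDataset(cfg, d2, seed = 9L)
  m1 <- file.path(d1, "manifest.csv"); m2 <- file.path(d2, "manifest.csv")
  expect_identical(readBin(m1, "raw", file.size(m1)),
                   readBin(m2, "raw", file.size(m2)))
  f1 <- list.files(file.path(d1, "images"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "images"), full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  md3 <- buildSmokeDataset(cfg, tempfile(), seed = 10L)
  expect_false(identical(tools::md5sum(m1)[[1]],
                         tools::md5sum(file.path(md3@dir, "manifest.csv"))[[1]]))
  unlink(c(d1, d2, md3@dir), recursive = TRUE)
})

test_that("manifests round-trip through disk", {
  md <- sharedTinyDataset()
  rt <- readManifest(md@dir)
  expect_equal(manifestRecords(rt), manifestRecords(md))
  expect_equal(manifestCounts(rt), manifestCounts(md))
})

test_that("YAML dataset configurations are honored", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("total: 25", "smoke_fraction: 0.2", "test_fraction: 0.2",
               "height: 48", "width: 64"), p)
  cfg <- readDatasetConfig(p)
  expect_equal(cfg$total, 25L)
  expect_equal(cfg$height, 48L)
  expect_equal(cfg$width, 64L)
  expect_equal(cfg$testFraction, 0.2)
})
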