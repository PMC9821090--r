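test_that("binarization separates a bimodal image exactly", {
  set.seed(21)
  px <- matrix(40, 128, 128)
  vess <- matrix(runif(128^2) < 0.3, 128, 128)
  px[vess] <- 200
  m <- binarizeVasculature(EnFaceImage(px))
  expect_identical(pixels(m), vess)
  expect_error(binarizeVasculature(EnFaceImage(matrix(9, 64, 64))),
               "constant")
})

test_that("binarized vessel fraction tracks the generator's drawn fraction", {
  scene <- renderScene(syntheticSpec(size = 512, seed = 1))
  m <- binarizeVasculature(sceneImage(scene))
  frac <- mean(pixels(m))
  expect_lt(abs(frac - scene@vesselFraction) / scene@vesselFraction, 0.10)
})

test_that("successive dilations bridge gaps and match brute force", {
  m <- matrix(FALSE, 16, 16)
  m[8, 5] <- TRUE
  m[8, 11] <- TRUE                           # 6 px apart
  msk <- RegionMask(m)
  expect_equal(nComponents8(pixels(closeVesselGaps(msk, 2))), 2L)
  expect_equal(nComponents8(pixels(closeVesselGaps(msk, 3))), 1L)
  expect_identical(pixels(closeVesselGaps(msk, 3)),
                   bruteMorph3(m, "dilate", 3))
  expect_identical(pixels(closeVesselGaps(msk, 0)), m)
  full <- RegionMask(matrix(TRUE, 8, 8))
  expect_identical(pixels(closeVesselGaps(full, 4)), pixels(full))
})

test_that("avascular recovery complements eroded vessels", {
  full <- RegionMask(matrix(TRUE, 32, 32))
  expect_false(any(pixels(recoverFazRegion(full, 5))))

  # dilate k then erode k on a convex blob recovers it almost exactly
  disk <- diskMask(256, 100)
  closed <- closeVesselGaps(RegionMask(disk), 5)
  rec <- recoverFazRegion(closed, 5)
  expect_gte(jaccardIndex(RegionMask(disk), RegionMask(!pixels(rec))), 0.98)
})

test_that("morphology matches brute force on random masks", {
  for (seed in 1:25) {
    m <- randomMask(seed, size = 32L)
    msk <- RegionMask(m)
    expect_identical(pixels(closeVesselGaps(msk, 1)),
                     bruteMorph3(m, "dilate"), info = paste("dilate", seed))
    expect_identical(pixels(recoverFazRegion(msk, 1)),
                     !bruteMorph3(m, "erode"), info = paste("erode", seed))
    expect_identical(pixels(closeVesselGaps(msk, 2)),
                     bruteMorph3(m, "dilate", 2), info = paste("dilate2", seed))
  }
})

test_that("particle analysis keeps the size-gated central component", {
  m <- matrix(FALSE, 1024, 1024)
  m[10:19, 10:19] <- TRUE                       # 100 px, below gate
  m[468:557, 468:557] <- TRUE                   # 8100 px, centered, in gate
  m[560:1009, 560:1009] <- TRUE                 # 202500 px, above gate
  sel <- selectFazComponent(RegionMask(m), ksmParams())
  expect_equal(sum(pixels(sel)), 8100)
  expect_true(all(which(pixels(sel), arr.ind = TRUE)[, 1] %in% 468:557))
})

test_that("extraction failure carries a component census", {
  err <- tryCatch(selectFazComponent(RegionMask(matrix(FALSE, 64, 64))),
                  error = function(e) e)
  expect_s3_class(err, "fazExtractionError")
  expect_length(err$census, 0)

  m <- matrix(FALSE, 64, 64)
  m[2:4, 2:4] <- TRUE
  err <- tryCatch(selectFazComponent(RegionMask(m), ksmParams()),
                  error = function(e) e)
  expect_s3_class(err, "fazExtractionError")
  expect_equal(err$census, 9L)
})

test_that("center policy prefers the component nearest the image center", {
  m <- matrix(FALSE, 256, 256)
  m[113:142, 113:142] <- TRUE                   # centered, 900 px
  m[3:32, 3:32] <- TRUE                         # cornered, 900 px
  p <- ksmParams(particleMinPx = 100, particleMaxPx = 1e6)
  sel <- selectFazComponent(RegionMask(m), p)
  expect_true(pixels(sel)[128, 128])
  expect_false(pixels(sel)[10, 10])
})

test_that("hole filling repairs perforated components", {
  m <- matrix(FALSE, 128, 128)
  m[40:90, 40:90] <- TRUE
  m[60:62, 60:62] <- FALSE
  p <- ksmParams(particleMinPx = 100, particleMaxPx = 1e6)
  sel <- selectFazComponent(RegionMask(m), p)
  expect_equal(sum(pixels(sel)), 51^2)
})

test_that("enlargement is a Euclidean distance band", {
  one <- matrix(FALSE, 33, 33)
  one[17, 17] <- TRUE
  out <- enlargeRegion(RegionMask(one), 4)
  expect_equal(sum(pixels(out)), 49)     # lattice points with d <= 4
  expect_identical(pixels(out), bruteEnlarge(one, 4))
  expect_identical(pixels(enlargeRegion(RegionMask(one), 0)), one)

  for (seed in 1:10) {
    m <- randomBlob(seed, size = 32L, ndisks = 3L, rmin = 2, rmax = 5)
    out <- suppressWarnings(enlargeRegion(RegionMask(m), 3))
    expect_identical(pixels(out), bruteEnlarge(m, 3),
                     info = paste("enlarge", seed))
  }
})

test_that("enlarging a disk grows area by about perimeter times radius", {
  disk <- diskMask(256, 100)
  out <- enlargeRegion(RegionMask(disk), 4)
  growth <- sum(pixels(out)) - sum(disk)
  expected <- 2 * pi * 100 * 4               # perimeter times band width
  expect_lt(abs(growth - expected) / expected, 0.05)
})

test_that("enlargement clipped at the frame warns", {
  m <- matrix(FALSE, 32, 32)
  m[2:6, 2:6] <- TRUE
  expect_warning(enlargeRegion(RegionMask(m), 4), "border")
})

test_that("foreground is monotone in dilation count and enlargement", {
  m <- randomMask(42, 32)
  prev <- -1
  for (n in 0:3) {
    cur <- sum(pixels(closeVesselGaps(RegionMask(m), n)))
    expect_gte(cur, prev)
    prev <- cur
  }
  blob <- RegionMask(randomBlob(7, size = 40L))
  prev <- -1
  for (e in c(0, 1, 2, 4)) {
    cur <- sum(pixels(suppressWarnings(enlargeRegion(blob, e))))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("full extraction recovers the synthetic ground truth", {
  scene <- renderScene(syntheticSpec(size = 512, seed = 7))
  res <- extractFaz(sceneImage(scene))
  expect_s4_class(res, "FazResult")
  expect_gte(jaccardIndex(fazMask(res), truthMask(scene)), 0.90)
  expect_equal(fazArea(res), pixelCount(res) * mmPerPixel(fazMask(res))^2)
  # the selected region is one filled component
  p <- pixels(fazMask(res))
  expect_equal(nComponents8(p[seq(1, 512, by = 4), seq(1, 512, by = 4)]), 1L)
})

test_that("extraction is deterministic", {
  scene <- renderScene(syntheticSpec(size = 256, seed = 3))
  a <- extractFaz(sceneImage(scene))
  b <- extractFaz(sceneImage(scene))
  expect_identical(pixels(fazMask(a)), pixels(fazMask(b)))
  expect_identical(fazArea(a), fazArea(b))
})

test_that("an all-vessel image fails extraction with stage provenance", {
  set.seed(8)
  px <- matrix(200, 256, 256) + matrix(runif(256^2, 0, 55), 256, 256)
  err <- tryCatch(extractFaz(EnFaceImage(round(px)), bandpass = NULL),
                  error = function(e) e)
  expect_s3_class(err, "fazExtractionError")
  expect_match(conditionMessage(err), "\\[select\\]")
})

test_that("a broken FAZ border is still recovered simply connected", {
  scene <- renderScene(syntheticSpec(size = 512, seed = 5, gapRate = 0.3))
  res <- extractFaz(sceneImage(scene))
  p <- pixels(fazMask(res))
  filled <- EBImage::fillHull(matrix(as.numeric(p), nrow(p), ncol(p))) > 0.5
  expect_identical(p, matrix(filled, nrow(p), ncol(p)))
  expect_gte(jaccardIndex(fazMask(res), truthMask(scene)), 0.85)
})
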