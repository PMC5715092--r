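# Synthetic plate generator: occupancy sampling, rendering, manifests.

test_that("cell counts follow the occupancy model", {
  # degenerate rate
  set.seed(1)
  expect_true(all(sampleCellCount(occupancyModel(lambda = 0,
                                                 clusterExcess = 0),
                                  1000L) == 0L))

  # pure Poisson: empirical P(0) within 3 standard errors of the pmf
  lam <- 0.202247
  n <- 2e5
  set.seed(2)
  cnt <- sampleCellCount(occupancyModel(lambda = lam, clusterExcess = 0), n)
  p0 <- exp(-lam)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(cnt == 0) - p0), 3 * se)

  # goodness of fit of the whole distribution at the 1% level
  grp <- pmin(cnt, 4)
  probs <- c(dpois(0:3, lam), 1 - ppois(3, lam))
  gof <- suppressWarnings(chisq.test(tabulate(grp + 1L, 5L), p = probs))
  expect_gt(gof$p.value, 0.01)

  # full cluster excess: every nonzero draw is incremented, so a count of
  # exactly 1 is impossible while empty wells survive
  set.seed(3)
  cnt1 <- sampleCellCount(occupancyModel(lambda = 0.2, clusterExcess = 1),
                          5e4)
  expect_false(any(cnt1 == 1L))
  expect_gt(mean(cnt1 == 0L), 0.5)
  # and the two-stage rule shifts Poisson mass k -> k+1 for k >= 1
  expect_lt(abs(mean(cnt1 == 2L) - dpois(1, 0.2)),
            3 * sqrt(dpois(1, 0.2) / 5e4) + 3e-3)
})

test_that("rendering draws the requested cells inside the well", {
  for (shape in c("square", "round")) {
    geom <- smallGeometry(shape, 128L)
    for (count in c(0L, 1L, 2L, 3L)) {
      set.seed(100 + count)
      img <- renderWell(count, geom, cleanArtifacts())
      expect_true(all(img >= 0 & img <= 255))
      expect_identical(dim(img), c(128L, 128L))
      # connected-component oracle on the clean render
      expect_identical(countBlobs(img), count)
    }
    # empty clean well contains only wall and background levels
    set.seed(99)
    img0 <- renderWell(0L, geom, cleanArtifacts())
    expect_true(all(img0 %in% c(geom@backgroundIntensity,
                                geom@wallIntensity)))
  }
})

test_that("rendering is a pure function of inputs and seed", {
  geom <- smallGeometry("round")
  art <- artifactModel()
  set.seed(42)
  a <- renderWell(2L, geom, art)
  set.seed(42)
  b <- renderWell(2L, geom, art)
  expect_identical(a, b)
})

test_that("overcrowded geometry fails with a bounded-attempts error", {
  tiny <- wellGeometry("round", imageSide = 64L, wallThickness = 26)
  set.seed(5)
  expect_error(renderWell(5L, tiny, cleanArtifacts()),
               "non-overlapping")
})

test_that("generatePlate writes labeled images and a lossless manifest", {
  dir <- withr::local_tempdir()
  geom <- smallGeometry()
  pl <- generatePlate(10L, geom, occupancyModel(), artifactModel(),
                      seed = 7, plateId = "tp", dir = dir)
  info <- wellInfo(pl)
  expect_identical(nrow(info), 10L)
  expect_true(all(file.exists(file.path(dir, info$filename))))
  # labels equal counts clipped into the four categories
  expect_identical(as.character(info$category),
                   as.character(countToCategory(info$count)))
  # manifest round-trips losslessly
  back <- readManifest(file.path(dir, "tp_manifest.tsv"))
  expect_identical(back$well_id, info$well_id)
  expect_identical(back$count, info$count)
  expect_identical(back$category, as.character(info$category))
  expect_identical(as.logical(back$debris), info$debris)
  # determinism: identical seed, identical manifest and pixels
  pl2 <- generatePlate(10L, geom, occupancyModel(), artifactModel(),
                       seed = 7, plateId = "tp")
  expect_identical(wellInfo(pl2)[, -3], info[, -3])
  expect_identical(wellImages(pl2)[[1]],
                   matrix(as.integer(round(png::readPNG(
                     file.path(dir, info$filename[1])) * 255)), 64L))
})

test_that("plate category frequencies match the occupancy distribution", {
  lam <- 0.202247
  pl <- generatePlate(3984L, smallGeometry(),
                      occupancyModel(lambda = lam, clusterExcess = 0),
                      cleanArtifacts(), seed = 11, plateId = "big",
                      keepImages = FALSE)
  f0 <- mean(wellCategories(pl) == "0")
  p0 <- exp(-lam)
  expect_lt(abs(f0 - p0), 3 * sqrt(p0 * (1 - p0) / 3984))
})
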