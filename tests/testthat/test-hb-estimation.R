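# hand-built fixture: 128x128 image, circular disc, rectangular "vessel"
# block of known color; lets the Hb index be checked against arithmetic
fixtureImage <- function(tissueCol, vesselCol = c(0.44, 0.2475, 0.136)) {
  px <- array(0, c(128, 128, 3))
  for (ch in 1:3) px[, , ch] <- tissueCol[ch]
  vmask <- matrix(FALSE, 128, 128)
  vmask[55:74, 55:74] <- TRUE  # 400 px block at the disc center
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[vmask] <- vesselCol[ch]
    px[, , ch] <- plane
  }
  disc <- new("DiscGeometry", center = c(64.5, 64.5), radiusX = 40,
              radiusY = 40, eye = "right")
  img <- FundusImage(px)
  list(img = img, regions = makeRegions(disc, vmask, dim = c(128, 128)))
}

test_that("Hb index hits its defining anchor points", {
  # achromatic tissue (r = g): Hb is exactly 0
  f <- fixtureImage(c(0.7, 0.7, 0.6))
  hb <- estimateHbMap(f$img, f$regions)
  expect_equal(unique(hbValues(hb)[tissueMask(f$regions)]), 0)

  # tissue colored exactly like the vessel medians: Hb is exactly 100
  f2 <- fixtureImage(c(0.44, 0.2475, 0.136))
  hb2 <- estimateHbMap(f2$img, f2$regions)
  expect_equal(unique(hbValues(hb2)[tissueMask(f2$regions)]), 100)
  # and vessel pixels carry 100 by definition
  expect_equal(unique(hbValues(hb2)[vesselMask(f2$regions)]), 100)

  # green-dominant vessels are an invalid reference
  f3 <- fixtureImage(c(0.7, 0.5, 0.5), vesselCol = c(0.3, 0.5, 0.3))
  expect_error(estimateHbMap(f3$img, f3$regions), "not red-dominant")
})

test_that("lens compensation recovers the attenuation factor", {
  # clear lens: kappaHat = 1 within 0.05, compensation is the identity
  r1 <- renderFundus(subjectSpec(size = 256, seed = 12, kappa = 1))
  reg1 <- makeRegions(r1$disc, r1$vessels)
  c1 <- estimateLensCompensation(r1$image, reg1)
  expect_lt(abs(kappaHat(c1) - 1), 0.05)
  expect_lt(abs(greenScale(c1) - 1), 0.03)

  # kappa = 0.7 recovered within 0.1
  r2 <- renderFundus(subjectSpec(size = 256, seed = 12, kappa = 0.7))
  reg2 <- makeRegions(r2$disc, r2$vessels)
  c2 <- estimateLensCompensation(r2$image, reg2)
  expect_lt(abs(kappaHat(c2) - 0.7), 0.1)

  # degenerate all-zero blue channel: clamped to the floor and flagged
  px <- fundusPixels(r1$image)
  px[, , 3] <- 0
  c3 <- estimateLensCompensation(FundusImage(px), reg1)
  expect_equal(kappaHat(c3), 0.05)
  expect_true(c3@flagged)

  # too few vessel pixels is a reference failure
  few <- makeRegions(r1$disc,
                     matrix(FALSE, 256, 256), dim = c(256, 256))
  expect_error(estimateLensCompensation(r1$image, few), "vessel pixels")
})

test_that("estimates track a red-cell dilution series nearly linearly", {
  base <- subjectSpec(size = 256, seed = 21, noiseSd = 0)
  ds <- dilutionSeries(c(0.2, 0.4, 0.6, 0.8), base)
  est <- tru <- numeric(length(ds$levels))
  sect <- matrix(NA_real_, length(ds$levels), 24)
  for (i in seq_along(ds$levels)) {
    r <- ds$renders[[i]]
    fit <- suppressWarnings(analyzeFundus(r$image))
    est[i] <- meanHb(fit$profile)
    sect[i, ] <- sectorHb(fit$profile)
    tru[i] <- mean(r$trueHb[r$tissue])
  }
  expect_true(all(diff(est) > 0))
  expect_gt(summary(lm(est ~ tru))$r.squared, 0.95)
  # sector-level monotonicity in true Hb
  expect_true(all(apply(sect, 2, function(s) all(diff(s) > -1e-9))))
})

test_that("sector monotonicity holds across dilution levels and seeds", {
  for (seed in 1:10) {
    ds <- dilutionSeries(c(0.25, 0.5, 0.75),
                         smallSpec(seed = seed, noiseSd = 0))
    sect <- sapply(ds$renders, function(r)
      sectorHb(suppressWarnings(analyzeFundus(r$image))$profile))
    ok <- apply(sect, 1, function(s) all(is.na(s)) ||
                  all(diff(s[!is.na(s)]) > -1e-9))
    expect_true(all(ok))
  }
})

test_that("the Hb index cancels global illumination changes", {
  r <- renderFundus(subjectSpec(size = 256, seed = 30))
  ref <- meanHb(suppressWarnings(analyzeFundus(r$image))$profile)
  for (s in c(0.6, 0.8)) {
    scaled <- FundusImage(fundusPixels(r$image) * s, eye = eyeSide(r$image))
    expect_lt(abs(meanHb(suppressWarnings(analyzeFundus(scaled))$profile) - ref), 1)
  }
})

test_that("lens compensation bounds the yellowing-induced Hb shift", {
  ref <- meanHb(suppressWarnings(analyzeFundus(
    renderFundus(subjectSpec(size = 256, seed = 31, kappa = 1))$image
  ))$profile)
  for (k in c(0.7, 0.85)) {
    rk <- renderFundus(subjectSpec(size = 256, seed = 31, kappa = k))
    withComp <- abs(meanHb(suppressWarnings(
      analyzeFundus(rk$image))$profile) - ref)
    without <- abs(meanHb(suppressWarnings(analyzeFundus(
      rk$image, lensComp = FALSE))$profile) - ref)
    expect_lte(withComp, 2)
    expect_gt(without, withComp)
  }
})

test_that("pseudoimages render deterministically and decode back", {
  r <- renderFundus(smallSpec(seed = 7))
  fit <- suppressWarnings(analyzeFundus(r$image))
  hb <- fit$hb

  # uniform map: a single palette color over the disc
  uni <- hb
  uni@values[!is.na(uni@values)] <- 50
  pu <- renderPseudoimage(uni)
  inside <- !is.na(uni@values)
  cols <- unique(cbind(pu$raster[, , 1][inside], pu$raster[, , 2][inside],
                       pu$raster[, , 3][inside]))
  expect_equal(nrow(cols), 1)

  # tissue rendering is a function of tissue values only
  alt <- hb
  alt@values[vesselMask(hb@regions)] <- 42
  pa <- renderPseudoimage(alt)
  pb <- renderPseudoimage(hb)
  tm <- tissueMask(hb@regions)
  for (ch in 1:3)
    expect_identical(pa$raster[, , ch][tm], pb$raster[, , ch][tm])

  # palette inversion: decoded values within one Hb unit
  dec <- decodePseudoimage(pb$raster)
  expect_lt(max(abs(dec[inside] - hb@values[inside])), 1)
  expect_true(all(is.na(dec[!inside])))
})
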