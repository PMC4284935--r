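discFixture <- function(r = 30, size = 96, eye = "right", ry = r) {
  new("DiscGeometry", center = c(size / 2, size / 2), radiusX = r,
      radiusY = ry, eye = eye)
}

test_that("the sector map realizes 8 wedges x 3 rings with the polar oracle", {
  for (eye in c("right", "left")) {
    disc <- discFixture(eye = eye)
    sm <- buildSectorMap(disc, c(96, 96))
    lab <- sectorLabels(sm)
    expect_setequal(setdiff(unique(as.vector(lab)), 0L), 1:24)

    # every pixel re-labeled by the independent per-pixel polar formula
    oracle <- matrix(0L, 96, 96)
    for (y in 1:96) for (x in 1:96)
      oracle[y, x] <- naiveSectorLabel(x, y, 48, 48, 30, 30, eye)
    expect_identical(lab, oracle)
  }
  # oblique ellipse: labels still partition the interior
  disc <- discFixture(r = 34, ry = 26)
  lab <- sectorLabels(buildSectorMap(disc, c(96, 96)))
  expect_setequal(setdiff(unique(as.vector(lab)), 0L), 1:24)

  # clipped disc is an error
  expect_error(buildSectorMap(discFixture(r = 50), c(96, 96)), "clipped")
})

test_that("ring geometry splits areas 1:3:5 and outer ring is mod 3", {
  disc <- discFixture(r = 40, size = 128)
  lab <- sectorLabels(buildSectorMap(disc, c(128, 128)))
  interiorN <- sum(lab > 0)
  innerN <- sum(lab %in% seq(1, 24, by = 3))
  expect_lt(abs(innerN / interiorN - 1 / 9), 0.04 / 9)
  # labels occurring in the outer ring are exactly the multiples of 3
  X <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  Y <- matrix(seq_len(128), 128, 128)
  rho <- sqrt((X - 64)^2 + (Y - 64)^2) / 40
  outer <- lab[rho > 2 / 3 + 0.02 & rho < 1 - 0.02]
  expect_setequal(unique(outer), seq(3L, 24L, by = 3L))
})

test_that("sector aggregation matches a naive pixel loop exactly", {
  disc <- discFixture(r = 14, size = 64)
  sm <- buildSectorMap(disc, c(64, 64))
  interior <- sectorLabels(sm) > 0
  set.seed(3)
  vessels <- interior & matrix(runif(64 * 64) < 0.15, 64)
  reg <- makeRegions(disc, vessels)
  values <- matrix(NA_real_, 64, 64)
  values[interior] <- round(runif(sum(interior), 0, 120), 3)
  values[vessels] <- 100
  hb <- new("HbMap", values = values, vesselReference = c(r = .5, g = .3),
            regions = reg, valid = TRUE)
  prof <- suppressWarnings(aggregateSectors(hb, sm))
  o <- naiveSectorStats(values, sectorLabels(sm), tissueMask(reg))
  expect_equal(sectorHb(prof), o$means, tolerance = 1e-12)
  expect_equal(sectorCounts(prof), as.numeric(o$counts))
  # partition: counts add up to the tissue area exactly
  expect_equal(sum(sectorCounts(prof)), sum(tissueMask(reg)))
  # weighted-mean identity
  ok <- !is.na(sectorHb(prof))
  expect_equal(meanHb(prof),
               sum(sectorHb(prof)[ok] * sectorCounts(prof)[ok]) /
                 sum(sectorCounts(prof)[ok]), tolerance = 1e-9)
})

test_that("constant and ring-structured maps aggregate as constructed", {
  disc <- discFixture(r = 30, size = 96)
  sm <- buildSectorMap(disc, c(96, 96))
  interior <- sectorLabels(sm) > 0
  reg <- makeRegions(disc, matrix(FALSE, 96, 96))

  uni <- matrix(NA_real_, 96, 96); uni[interior] <- 70
  hbU <- new("HbMap", values = uni, vesselReference = c(r = .5, g = .3),
             regions = reg, valid = TRUE)
  pU <- aggregateSectors(hbU, sm)
  expect_equal(sectorHb(pU), rep(70, 24))
  expect_equal(meanHb(pU), 70)

  # inner ring 30, elsewhere 80: sectors = 1 mod 3 report 30, others 80
  two <- matrix(NA_real_, 96, 96)
  two[interior] <- ifelse(sectorLabels(sm)[interior] %% 3 == 1, 30, 80)
  hbT <- new("HbMap", values = two, vesselReference = c(r = .5, g = .3),
             regions = reg, valid = TRUE)
  pT <- aggregateSectors(hbT, sm)
  expect_equal(sectorHb(pT)[seq(1, 24, by = 3)], rep(30, 8))
  expect_equal(sectorHb(pT)[-seq(1, 24, by = 3)], rep(80, 16))
})

test_that("profile mirroring is an involution that fixes the reference frame", {
  mk <- function(eye, frame) new("SectorProfile", meanHb = 60,
    sectorHb = as.numeric(1:24), sectorCounts = rep(10, 24),
    subjectId = "m", eye = eye, frame = frame)

  # right-eye profile: unchanged
  pr <- mk("right", "screen")
  expect_equal(sectorHb(mirrorProfile(pr)), as.numeric(1:24))

  # screen-frame left eye: wedge w swaps with wedge 9 - w, rings kept
  pl <- mk("left", "screen")
  ml <- mirrorProfile(pl)
  for (s in 1:24) {
    w <- (s - 1) %/% 3 + 1; ring <- (s - 1) %% 3 + 1
    expect_equal(sectorHb(ml)[3 * (9 - w - 1) + ring], s)
  }
  expect_identical(ml@frame, "anatomical")

  # involution
  expect_equal(sectorHb(mirrorProfile(ml)), sectorHb(ml))
  set.seed(5)
  rnd <- mk("left", "screen"); rnd@sectorHb <- runif(24, 0, 100)
  expect_equal(sectorHb(mirrorProfile(mirrorProfile(rnd))),
               sectorHb(mirrorProfile(rnd)))
})

test_that("left and right renders of one subject align anatomically", {
  hbs <- hbSectorDefaults()$healthyMean
  pr <- suppressWarnings(analyzeFundus(renderFundus(
    subjectSpec(size = 256, seed = 40, eye = "right",
                trueSectorHb = hbs))$image))$profile
  pl <- suppressWarnings(analyzeFundus(renderFundus(
    subjectSpec(size = 256, seed = 40, eye = "left",
                trueSectorHb = hbs))$image))$profile
  ok <- !is.na(sectorHb(pr)) & !is.na(sectorHb(pl))
  expect_gt(sum(ok), 20)
  expect_lt(max(abs(sectorHb(pr)[ok] - sectorHb(pl)[ok])), 6)
})
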