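# Forward optical model endmembers (normalized reflectance).
# Disc tissue is a linear mix of a pale achromatic endmember (r = g so that
# Hb = 0 tissue has zero red-green contrast) and a red-dominant blood
# endmember. The blood blue:green ratio equals the clear-lens vessel
# calibration constant (0.55) used by the lens compensation. The blood red
# is deliberately not equal to the pale red, so the generator is not the
# inverse of the vessel-normalized estimator.
.PALE <- c(0.88, 0.88, 0.85)
.BLOOD <- c(0.80, 0.45, 0.2475)
.VESSEL_SHADE <- 0.55   # vessels: blood color at darker value
.BACKGROUND <- c(0.55, 0.26, 0.13)  # peripapillary retina

#' Per-sector Hb generator defaults for the two groups
#'
#' Packaged per-sector Hb means and standard deviations (percent) for the
#' healthy and Parkinson groups - the study conditions the synthetic
#' cohort generator emulates.
#'
#' @return data.frame with columns `sector`, `healthyMean`, `healthySd`,
#'   `pdMean`, `pdSd`.
#' @export
hbSectorDefaults <- function() {
  data.frame(
    sector = 1:24,
    healthyMean = c(74, 73, 68, 71, 74, 68, 64, 71, 69, 57, 58, 61,
                    57, 54, 58, 60, 64, 67, 67, 77, 76, 73, 84, 75),
    healthySd = c(16, 14, 12, 15, 13, 12, 17, 11, 11, 16, 17, 13,
                  17, 17, 15, 17, 17, 14, 19, 14, 11, 17, 13, 12),
    pdMean = c(70, 64, 56, 65, 64, 58, 60, 60, 56, 54, 49, 49,
               52, 47, 46, 57, 57, 57, 66, 69, 65, 71, 71, 64),
    pdSd = c(16, 16, 14, 18, 15, 24, 16, 14, 15, 12, 12, 12,
             16, 16, 12, 15, 14, 19, 19, 16, 18, 19, 19, 17))
}

#' RNFL generator defaults, Cirrus field layout
#'
#' Peripapillary RNFL thickness means/SDs (micrometers) per group: mean,
#' four quadrants and twelve clock-hour sectors (a 17-parameter family).
#'
#' @return data.frame with columns `parameter`, `healthyMean`, `healthySd`,
#'   `pdMean`, `pdSd`.
#' @export
rnflCirrusDefaults <- function() {
  data.frame(
    parameter = c("mean", "superior", "nasal", "inferior", "temporal",
                  paste0("h", 1:12)),
    healthyMean = c(105, 139, 80, 134, 66,
                    118, 101, 64, 75, 117, 149, 137, 70, 60, 78, 136, 126),
    healthySd = c(10, 19, 11, 21, 11,
                  23, 19, 10, 13, 22, 24, 26, 15, 10, 15, 23, 22),
    pdMean = c(93, 115, 73, 119, 65,
               102, 86, 56, 62, 94, 130, 129, 68, 55, 75, 130, 119),
    pdSd = c(10, 17, 13, 18, 13,
             15, 19, 11, 14, 16, 20, 24, 14, 10, 14, 22, 25))
}

#' RNFL generator defaults, Spectralis field layout
#'
#' Mean, four quadrants and four oblique sectors (a 9-parameter family).
#'
#' @return data.frame, same columns as [rnflCirrusDefaults()].
#' @export
rnflSpectralisDefaults <- function() {
  data.frame(
    parameter = c("mean", "superior", "nasal", "inferior", "temporal",
                  "superonasal", "inferonasal", "inferotemporal",
                  "superotemporal"),
    healthyMean = c(100, 123, 73, 133, 71, 126, 141, 108, 113),
    healthySd = c(10, 13, 13, 20, 11, 17, 18, 21, 15),
    pdMean = c(93, 115, 71, 122, 64, 122, 138, 99, 103),
    pdSd = c(10, 26, 26, 27, 23, 18, 18, 18, 19))
}

#' Construct a synthetic subject specification
#'
#' @param subjectId,group,eye metadata.
#' @param trueSectorHb 24 true sector Hb percentages (default: the healthy
#'   group sector means).
#' @param size canvas side(s) in pixels (default 512).
#' @param center disc center `(x, y)` (default: canvas center).
#' @param radiusX,radiusY disc semi-axes (default 80 and 76 px at the
#'   512 px canvas).
#' @param nBranches vessel branches (default 6).
#' @param vesselWidth trunk width in px (default `max(3.5, 0.05 *
#'   radiusX)`; narrower vessels would not survive the 3x3 opening used by
#'   the segmenter).
#' @param illumAmplitude relative amplitude of the linear illumination
#'   gradient (default 0.10).
#' @param kappa lens blue-attenuation factor, 1 = clear lens (the packaged
#'   cohorts default to clear media, matching the usual inclusion
#'   criterion).
#' @param noiseSd additive Gaussian sensor noise SD (default 0.01, about
#'   2.5 steps of an 8-bit camera).
#' @param seed RNG seed for the render.
#' @return a [SubjectSpec-class].
#' @export
subjectSpec <- function(subjectId = "synthetic", group = "healthy",
                        eye = "right",
                        trueSectorHb = hbSectorDefaults()$healthyMean,
                        size = 512, center = NULL,
                        radiusX = 0.15625 * max(size),
                        radiusY = 0.95 * radiusX,
                        nBranches = 6,
                        vesselWidth = max(3.5, 0.05 * radiusX),
                        illumAmplitude = 0.1, kappa = 1, noiseSd = 0.01,
                        seed = 1) {
  if (length(size) == 1L) size <- c(size, size)
  if (is.null(center)) center <- c(size[2] / 2, size[1] / 2)
  new("SubjectSpec", subjectId = subjectId, group = group, eye = eye,
      trueSectorHb = trueSectorHb, size = size, center = center,
      radiusX = radiusX, radiusY = radiusY, nBranches = nBranches,
      vesselWidth = vesselWidth, illumAmplitude = illumAmplitude,
      kappa = kappa, noiseSd = noiseSd, seed = seed)
}

# rasterize one thick segment into a logical mask (in place, returned)
.paintSegment <- function(mask, x1, y1, x2, y2, w) {
  H <- nrow(mask); W <- ncol(mask)
  half <- w / 2 + 1
  xr <- .clamp(floor(min(x1, x2) - half), 1, W):.clamp(
    ceiling(max(x1, x2) + half), 1, W)
  yr <- .clamp(floor(min(y1, y2) - half), 1, H):.clamp(
    ceiling(max(y1, y2) + half), 1, H)
  px <- matrix(xr, length(yr), length(xr), byrow = TRUE)
  py <- matrix(yr, length(yr), length(xr))
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- max(dx^2 + dy^2, 1e-9)
  tt <- .clamp(((px - x1) * dx + (py - y1) * dy) / L2, 0, 1)
  d2 <- (px - x1 - tt * dx)^2 + (py - y1 - tt * dy)^2
  sub <- mask[yr, xr, drop = FALSE]
  mask[yr, xr] <- sub | (d2 <= (w / 2)^2)
  mask
}

# branching vessel tree from the disc center; uses the current RNG stream
.drawVesselTree <- function(spec) {
  H <- spec@size[1]; W <- spec@size[2]
  mask <- matrix(FALSE, H, W)
  if (spec@nBranches < 1) return(mask)  # avascular disc (test fixture)
  cx <- spec@center[1]; cy <- spec@center[2]
  w0 <- spec@vesselWidth
  # central trunk
  mask <- .paintSegment(mask, cx, cy - 0.3 * spec@radiusY,
                        cx, cy + 0.3 * spec@radiusY, 1.2 * w0)
  nB <- spec@nBranches
  angles <- (seq_len(nB) - 0.5) / nB * 2 * pi + runif(nB, -0.25, 0.25)
  for (b in seq_len(nB)) {
    x <- cx + runif(1, -0.1, 0.1) * spec@radiusX
    y <- cy + runif(1, -0.1, 0.1) * spec@radiusY
    th <- angles[b]
    w <- w0
    step <- 1.7 * spec@radiusX / 5
    for (s in 1:5) {
      x2 <- x + step * cos(th)
      y2 <- y + step * sin(th)
      mask <- .paintSegment(mask, x, y, x2, y2, w)
      x <- x2; y <- y2
      th <- th + rnorm(1, 0, 0.15)
      w <- w * 0.88
    }
  }
  mask
}

#' Render a synthetic fundus photograph with ground truth
#'
#' Deterministic forward model given the spec (including its seed):
#' a background retina color; disc tissue colored per pixel as a linear
#' mix between a pale achromatic endmember and a red-dominant blood
#' endmember, weighted by the true Hb fraction (the sector-piecewise field,
#' smoothed within the disc by normalized Gaussian convolution); a
#' branching vessel tree drawn from the disc center at 100% Hb color and
#' darker value; a multiplicative linear illumination gradient; lens
#' yellowing multiplying blue by `kappa` and green by `(1 + kappa) / 2`;
#' and additive Gaussian sensor noise, clipped to \[0, 1\].
#'
#' @param spec a [SubjectSpec-class].
#' @return list with `image` ([FundusImage-class]), `disc`
#'   ([DiscGeometry-class], ground truth), `vessels` (true vessel mask
#'   clipped to the disc interior), `tissue` (true tissue mask), `trueHb`
#'   (matrix of true Hb percentages over tissue, `NA` elsewhere) and
#'   `sectorMap` (the [SectorMap-class] of the true geometry).
#' @examples
#' r <- renderFundus(subjectSpec(seed = 11))
#' r$image
#' mean(r$trueHb[r$tissue])
#' @export
renderFundus <- function(spec) {
  validObject(spec)
  H <- spec@size[1]; W <- spec@size[2]
  geom <- new("DiscGeometry", center = spec@center, radiusX = spec@radiusX,
              radiusY = spec@radiusY, eye = spec@eye)
  .checkInsideImage(geom, c(H, W))
  .withSeed(spec@seed, {
    interior <- .interiorMask(geom, c(H, W))
    smap <- buildSectorMap(geom, c(H, W))
    f <- matrix(0, H, W)
    f[interior] <- spec@trueSectorHb[smap@labels[interior]] / 100
    sigma <- max(1.5, 0.04 * spec@radiusX)
    num <- EBImage::gblur(f, sigma)
    den <- EBImage::gblur(interior + 0, sigma)
    fs <- matrix(0, H, W)
    fs[interior] <- .clamp(num[interior] / pmax(den[interior], 1e-6), 0, 1)

    vtree <- .drawVesselTree(spec)
    grids <- .coordGrids(c(H, W))
    illum <- 1 + spec@illumAmplitude *
      ((grids$x - (W + 1) / 2) / W + (grids$y - (H + 1) / 2) / H)
    lensF <- c(1, (1 + spec@kappa) / 2, spec@kappa)

    px <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(.BACKGROUND[ch], H, W)
      plane[interior] <- (1 - fs[interior]) * .PALE[ch] +
        fs[interior] * .BLOOD[ch]
      plane[vtree] <- .VESSEL_SHADE * .BLOOD[ch]
      px[, , ch] <- plane * illum * lensF[ch]
    }
    if (spec@noiseSd > 0)
      px <- px + rnorm(length(px), 0, spec@noiseSd)
    px <- .clamp(px, 0, 1)

    vessels <- vtree & interior
    tissue <- interior & !vtree
    trueHb <- matrix(NA_real_, H, W)
    trueHb[tissue] <- 100 * fs[tissue]
    list(image = FundusImage(px, bitDepth = 8L, eye = spec@eye,
                             subjectId = spec@subjectId),
         disc = geom, vessels = vessels, tissue = tissue, trueHb = trueHb,
         sectorMap = smap)
  })
}

#' Render a red-cell dilution series
#'
#' Images with identical geometry, vessels, illumination and noise seed in
#' which only the Hb field varies: every sector is set to `level * 100`
#' percent. This is the calibration fixture for the near-linearity of the
#' Hb index.
#'
#' @param levels Hb fractions in \[0, 1\].
#' @param baseSpec the shared [SubjectSpec-class].
#' @return list with `levels` and `renders` (one [renderFundus()] result
#'   per level).
#' @export
dilutionSeries <- function(levels, baseSpec = subjectSpec()) {
  stopifnot(all(levels >= 0 & levels <= 1))
  renders <- lapply(levels, function(lv) {
    sp <- baseSpec
    sp@trueSectorHb <- rep(lv * 100, 24)
    sp@subjectId <- sprintf("%s-dilution-%.3f", baseSpec@subjectId, lv)
    renderFundus(sp)
  })
  list(levels = levels, renders = renders)
}

#' Construct synthetic cohort parameters
#'
#' @param nPd,nHealthy group sizes (defaults 155 and 91).
#' @param hb per-sector Hb defaults ([hbSectorDefaults()]).
#' @param cirrus,spectralis RNFL defaults ([rnflCirrusDefaults()],
#'   [rnflSpectralisDefaults()]).
#' @param hoehnYahr `(mean, sd)` of the disease-severity stage for the PD
#'   group, truncated to \[1, 5\] at draw time (default 2.68, 0.82).
#' @param imageSize canvas side in px (default 512).
#' @param discRadius nominal disc semi-axis in px (default 80).
#' @param illumAmplitude,kappa,noiseSd forward-model nuisance parameters
#'   (defaults 0.1, 1 = clear lens, 0.01).
#' @param seed master seed; all subject-level draws and render seeds fan
#'   out from it reproducibly.
#' @return a [CohortParams-class].
#' @export
cohortParams <- function(nPd = 155, nHealthy = 91, hb = hbSectorDefaults(),
                         cirrus = rnflCirrusDefaults(),
                         spectralis = rnflSpectralisDefaults(),
                         hoehnYahr = c(2.68, 0.82), imageSize = 512,
                         discRadius = 0.15625 * imageSize,
                         illumAmplitude = 0.1, kappa = 1, noiseSd = 0.01,
                         seed = 1) {
  stopifnot(nPd >= 0, nHealthy >= 0, nPd + nHealthy >= 1,
            all(hb$healthySd >= 0), all(hb$pdSd >= 0), hoehnYahr[2] >= 0)
  new("CohortParams", nPd = nPd, nHealthy = nHealthy, hb = hb,
      cirrus = cirrus, spectralis = spectralis, hoehnYahr = hoehnYahr,
      imageSize = imageSize, discRadius = discRadius,
      illumAmplitude = illumAmplitude, kappa = kappa, noiseSd = noiseSd,
      seed = seed)
}

# truncated-normal draw by clamping (documented: slightly biases
# extreme-SD sectors toward the bounds)
.rtruncnorm <- function(n, mean, sd, lo, hi) .clamp(rnorm(n, mean, sd), lo, hi)

#' Draw a synthetic cohort with ground truth
#'
#' Per subject: true sector Hb values drawn `Normal(group mean, group SD)`
#' per sector, truncated to \[0, 100\]; RNFL fields drawn from the group
#' defaults; Hoehn-Yahr stage drawn truncated to \[1, 5\] for the disease
#' group; eye assigned at random; disc geometry jittered around the
#' nominal radius. Rendering specs (including per-subject seeds fanned out
#' from the master seed) are returned alongside the truth table; images
#' are rendered on demand by [renderFundus()] / [analyzeCohort()] so large
#' cohorts need not be held in memory.
#'
#' @param params a [CohortParams-class].
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(params) {
  hb <- params@hb
  n <- params@nHealthy + params@nPd
  group <- rep(c("healthy", "PD"), c(params@nHealthy, params@nPd))
  w <- .sectorAreaWeights()
  .withSeed(params@seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    rows <- vector("list", n)
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      pd <- group[i] == "PD"
      mu <- if (pd) hb$pdMean else hb$healthyMean
      sdv <- if (pd) hb$pdSd else hb$healthySd
      sect <- .rtruncnorm(24, mu, sdv, 0, 100)
      eye <- sample(c("right", "left"), 1)
      rX <- params@discRadius * runif(1, 0.92, 1.08)
      rY <- rX * runif(1, 0.88, 1.0)
      ctr <- c(params@imageSize / 2, params@imageSize / 2) +
        runif(2, -0.04, 0.04) * params@imageSize
      cir <- with(params@cirrus, .rtruncnorm(
        length(parameter), if (pd) pdMean else healthyMean,
        if (pd) pdSd else healthySd, 0, Inf))
      spe <- with(params@spectralis, .rtruncnorm(
        length(parameter), if (pd) pdMean else healthyMean,
        if (pd) pdSd else healthySd, 0, Inf))
      id <- sprintf("%s-%03d", if (pd) "pd" else "hc", i)
      specs[[i]] <- subjectSpec(
        subjectId = id, group = group[i], eye = eye, trueSectorHb = sect,
        size = params@imageSize, center = ctr, radiusX = rX, radiusY = rY,
        illumAmplitude = params@illumAmplitude, kappa = params@kappa,
        noiseSd = params@noiseSd, seed = seeds[i])
      row <- data.frame(subject_id = id, group = group[i], eye = eye,
                        true_mean_hb = sum(w * sect))
      row[paste0("true_hb_", 1:24)] <- as.list(sect)
      row[paste0("cirrus_", params@cirrus$parameter)] <- as.list(cir)
      row[paste0("spectralis_", params@spectralis$parameter)] <- as.list(spe)
      row$hoehn_yahr <- if (pd)
        .rtruncnorm(1, params@hoehnYahr[1], params@hoehnYahr[2], 1, 5)
      else NA_real_
      row$age <- if (pd) .rtruncnorm(1, 67.33, 5.5, 54, 80)
      else .rtruncnorm(1, 67.21, 5.5, 55, 79)
      row$sex <- sample(c("M", "F"), 1, prob = c(0.59, 0.41))
      row$disease_duration <- if (pd) .rtruncnorm(1, 8.52, 2.10, 2, 19)
      else NA_real_
      rows[[i]] <- row
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    new("SyntheticCohort", truth = truth, specs = specs, params = params)
  })
}
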