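#' Estimate the crystalline-lens yellowing compensation
#'
#' A yellowed lens attenuates short wavelengths: blue by a factor `kappa`
#' and green, which sits spectrally between blue and red, by
#' `(1 + kappa) / 2`. Because lens absorption acts proportionally on
#' vessels and tissue alike, the vessel pixels expose it: their observed
#' blue:green ratio, divided by the clear-lens vessel calibration ratio
#' `refRatio`, equals `2 * kappa / (1 + kappa)`, which is inverted for
#' `kappaHat`. The green correction passed downstream is the exact
#' multiplicative inverse of the assumed green coupling,
#' `greenScale = 2 / (1 + kappaHat)`, so compensation of a clear-lens image
#' is the identity.
#'
#' @param img a [FundusImage-class].
#' @param regions a [DiscRegions-class] with at least `minVessel` vessel
#'   pixels.
#' @param refRatio clear-lens vessel blue:green calibration ratio
#'   (default 0.55).
#' @param minVessel minimal vessel pixel count (default 50).
#' @return a [LensCompensation-class]; `kappaHat` is clamped to
#'   \[0.05, 1\] and the object flagged when the raw estimate falls
#'   outside by more than 0.05.
#' @export
estimateLensCompensation <- function(img, regions, refRatio = 0.55,
                                     minVessel = 50) {
  vm <- regions@vessels
  if (sum(vm) < minVessel)
    stop("lens compensation needs at least ", minVessel,
         " vessel pixels; got ", sum(vm))
  px <- img@pixels
  gv <- px[, , 2][vm]
  bv <- px[, , 3][vm]
  rho <- median(bv / pmax(gv, 1e-3))
  rhoP <- rho / refRatio
  kap <- if (rhoP >= 1.95) Inf else rhoP / (2 - rhoP)
  flagged <- !is.finite(kap) || kap < 0 || kap > 1.05 || kap < 0.05 * 0.999
  kapC <- .clamp(ifelse(is.finite(kap), kap, 1), 0.05, 1)
  new("LensCompensation", kappaHat = kapC, greenScale = 2 / (1 + kapC),
      flagged = isTRUE(flagged))
}

#' Convert disc reflectance into a per-pixel Hb percentage map
#'
#' Hb-rich tissue reflects proportionally more red than green light, so the
#' per-pixel index `h = (r - g~) / max(r, eps)` (with `g~` the
#' lens-compensated green) grows almost linearly with the Hb amount. The
#' central retinal vessels define the scale: they carry 100% Hb and see the
#' same illumination and media as the tissue, so
#' `Hb% = 100 * h_pixel / h_vessel`, where `h_vessel` is computed from the
#' per-channel vessel medians (robust to specular highlights). Because `h`
#' is a ratio within each pixel, a common multiplicative illumination
#' change cancels exactly. Tissue values are clamped to \[0, `ceiling`\]
#' (the ceiling is above 100: tissue redder than the vessel median is
#' possible under noise and is retained rather than destroyed); vessel
#' pixels carry the defined value 100; pixels outside the disc are `NA`.
#'
#' @param img a [FundusImage-class].
#' @param regions a [DiscRegions-class].
#' @param comp a [LensCompensation-class], or `NULL` to disable lens
#'   compensation.
#' @param ceiling upper clamp of the tissue values (default 120).
#' @param eps division guard (default 1e-3).
#' @return an [HbMap-class].
#' @examples
#' r <- renderFundus(subjectSpec(seed = 3))
#' fit <- analyzeFundus(r$image)
#' fit$hb
#' @export
estimateHbMap <- function(img, regions, comp = NULL, ceiling = 120,
                          eps = 1e-3) {
  gs <- if (is.null(comp)) 1 else comp@greenScale
  px <- img@pixels
  vm <- regions@vessels
  tm <- regions@tissue
  if (!any(vm)) stop("no vessel pixels: vessel reference is not computable")
  r <- px[, , 1]
  g <- px[, , 2] * gs
  rv <- median(r[vm])
  gv <- median(px[, , 2][vm]) * gs
  hv <- (rv - gv) / max(rv, eps)
  if (hv <= 0)
    stop("invalid vessel reference: vessels are not red-dominant ",
         sprintf("(r=%.3f, g=%.3f)", rv, gv))
  h <- (r - g) / pmax(r, eps)
  vals <- .clamp(100 * h / hv, 0, ceiling)
  values <- matrix(NA_real_, nrow(r), ncol(r))
  values[tm] <- vals[tm]
  values[vm] <- 100
  new("HbMap", values = values, vesselReference = c(r = rv, g = gv),
      regions = regions, valid = rv > gv)
}

#' Render a false-color pseudoimage of an Hb map
#'
#' Deterministic mapping of the \[0, 120\] Hb scale onto a perceptually
#' ordered 256-level palette. Pixels outside the disc are rendered neutral
#' gray; vessels appear at their defined 100% level. A colorbar strip
#' annotated 0-120 accompanies the raster.
#'
#' @param hb an [HbMap-class].
#' @param palette an `hcl.colors` palette name (default `"Inferno"`).
#' @param nLevels palette resolution (default 256).
#' @return list with `raster` (`H x W x 3` array), `colorbar`
#'   (`nLevels x 16 x 3` strip, low at the bottom), `breaks` (the value of
#'   each level) and `palette`.
#' @seealso [decodePseudoimage()]
#' @export
renderPseudoimage <- function(hb, palette = "Inferno", nLevels = 256) {
  pal <- hcl.colors(nLevels, palette)
  rgb <- t(col2rgb(pal)) / 255
  breaks <- seq(0, 120, length.out = nLevels)
  vals <- hb@values
  idx <- pmin(nLevels, pmax(1, 1 + round(vals / 120 * (nLevels - 1))))
  out <- array(0.5, c(nrow(vals), ncol(vals), 3))
  inside <- !is.na(vals)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[inside] <- rgb[idx[inside], ch]
    out[, , ch] <- plane
  }
  bar <- array(0, c(nLevels, 16, 3))
  for (ch in 1:3) bar[, , ch] <- matrix(rev(rgb[, ch]), nLevels, 16)
  list(raster = out, colorbar = bar, breaks = breaks, palette = palette)
}

#' Decode a pseudoimage back to Hb values
#'
#' Inverts [renderPseudoimage()] by nearest-color lookup; useful for
#' validating renderings. Neutral (outside-disc) pixels return `NA`.
#'
#' @param raster `H x W x 3` array produced by [renderPseudoimage()].
#' @param palette,nLevels must match the rendering call.
#' @return numeric matrix of decoded Hb values.
#' @export
decodePseudoimage <- function(raster, palette = "Inferno", nLevels = 256) {
  pal <- t(col2rgb(hcl.colors(nLevels, palette))) / 255
  breaks <- seq(0, 120, length.out = nLevels)
  H <- dim(raster)[1]; W <- dim(raster)[2]
  flat <- matrix(raster, H * W, 3)
  neutral <- abs(flat[, 1] - 0.5) < 1e-9 & abs(flat[, 2] - 0.5) < 1e-9 &
    abs(flat[, 3] - 0.5) < 1e-9
  # nearest palette entry by squared distance, chunked to bound memory
  vals <- numeric(H * W)
  for (start in seq(1, H * W, by = 65536L)) {
    i <- start:min(start + 65535L, H * W)
    d <- outer(flat[i, 1], pal[, 1], "-")^2 +
         outer(flat[i, 2], pal[, 2], "-")^2 +
         outer(flat[i, 3], pal[, 3], "-")^2
    vals[i] <- breaks[max.col(-d, ties.method = "first")]
  }
  vals[neutral] <- NA_real_
  matrix(vals, H, W)
}
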