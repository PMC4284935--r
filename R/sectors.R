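# wedge index 1..8 and normalized elliptical radius for every pixel.
# Angle 0 is the temporal horizontal meridian; wedges advance clockwise on
# screen for right eyes and counterclockwise for left eyes (an x-mirror), so
# wedge 1 is the temporal-to-superotemporal octant in both eyes and indices
# are anatomically aligned across eyes.
.polarFields <- function(geom, dm) {
  e <- .ellipseNorm(geom, dm)
  sx <- if (geom@eye == "right") -1 else 1
  phi <- atan2(-e$dy, sx * e$dx) %% (2 * pi)
  wedge <- pmin(8L, 1L + as.integer(floor(phi / (pi / 4))))
  list(rho = sqrt(e$dx^2 + e$dy^2), wedge = wedge)
}

#' Build the 24-sector papillary partition
#'
#' Divides the disc into eight 45 degree radial wedges and three concentric
#' rings bounded at 1/3 and 2/3 of the disc radius (24 sectors in all).
#' Rings are scaled copies of the fitted ellipse - normalized elliptical
#' radius, not Euclidean - so oblique discs keep the 1/9 : 3/9 : 5/9 ring
#' area split. Labels are `3 * (wedge - 1) + ring` (ring 1 = inner), so the
#' outer ring is exactly the sector indices \{3, 6, 9, 12, 15, 18, 21,
#' 24\}. Wedges are counted from the temporal horizontal meridian,
#' clockwise for right eyes and counterclockwise for left eyes, mirroring
#' the clock-hour convention of peripapillary OCT so sector indices are
#' anatomically comparable across eyes.
#'
#' @param disc a [DiscGeometry-class] fully inside the image.
#' @param dim image dimensions `(H, W)`.
#' @return a [SectorMap-class].
#' @examples
#' disc <- new("DiscGeometry", center = c(128, 128), radiusX = 60,
#'             radiusY = 60, eye = "right")
#' sm <- buildSectorMap(disc, c(256, 256))
#' table(sectorLabels(sm))[-1]
#' @export
buildSectorMap <- function(disc, dim) {
  .checkInsideImage(disc, dim)
  pf <- .polarFields(disc, dim)
  ring <- 1L + (pf$rho > 1 / 3) + (pf$rho > 2 / 3)
  labels <- 3L * (pf$wedge - 1L) + ring
  labels[pf$rho > 1] <- 0L
  storage.mode(labels) <- "integer"
  new("SectorMap", labels = labels, geometry = disc,
      numbering = "wedge-major/ring-minor, temporal start, eye-mirrored")
}

#' Aggregate an Hb map over the 24 sectors
#'
#' Per-sector mean Hb over tissue pixels only (vessel pixels are excluded
#' from every aggregate: the disc is a two-region object and only the
#' tissue carries an estimate). `meanHb` is the mean over all tissue
#' pixels, i.e. the tissue-pixel-count-weighted mean of the sector values.
#' Sectors without any tissue pixel (e.g. fully vessel-covered) are
#' reported `NA` with a warning.
#'
#' @param hb an [HbMap-class].
#' @param smap a [SectorMap-class] congruent with the map.
#' @return a [SectorProfile-class] in the anatomical frame.
#' @export
aggregateSectors <- function(hb, smap) {
  if (!identical(dim(hb@values), dim(smap@labels)))
    stop("Hb map and sector map are not congruent")
  tm <- hb@regions@tissue
  lab <- smap@labels[tm]
  val <- hb@values[tm]
  counts <- tabulate(lab, nbins = 24L)
  sums <- numeric(24)
  rs <- rowsum(val, lab)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  sectorHb <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  if (any(counts == 0))
    warning("sectors without tissue pixels reported NA: ",
            paste(which(counts == 0), collapse = ", "))
  new("SectorProfile", meanHb = mean(val), sectorHb = as.numeric(sectorHb),
      sectorCounts = as.numeric(counts),
      subjectId = "anonymous", eye = smap@geometry@eye,
      frame = "anatomical")
}

# wedge reflection across the temporal meridian: wedge w <-> 9 - w,
# rings preserved
.mirrorPermutation <- function() {
  s <- 1:24
  w <- (s - 1L) %/% 3L + 1L
  ring <- (s - 1L) %% 3L + 1L
  3L * (9L - w - 1L) + ring
}

#' @describeIn mirrorProfile Profiles already in the anatomical frame (the
#'   output of [aggregateSectors()], whose sector map is eye-mirrored at
#'   labeling time) and right-eye profiles are returned unchanged. A
#'   left-eye profile recorded in native screen orientation is re-indexed
#'   by the wedge reflection `w -> 9 - w` (rings preserved) into the
#'   right-eye anatomical frame, so cohorts can mix eyes. Applying the
#'   function twice is the identity.
#' @export
setMethod("mirrorProfile", "SectorProfile", function(p) {
  if (p@frame == "anatomical" || p@eye == "right") {
    p@frame <- "anatomical"
    return(p)
  }
  perm <- .mirrorPermutation()
  new("SectorProfile", meanHb = p@meanHb,
      sectorHb = p@sectorHb[perm], sectorCounts = p@sectorCounts[perm],
      subjectId = p@subjectId, eye = p@eye, frame = "anatomical")
})
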