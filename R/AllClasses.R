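#' FundusImage: an RGB fundus photograph
#'
#' Raster container for a color fundus photograph. Pixel values are stored
#' channel-normalized to \[0, 1\] in an `height x width x 3` array (rows are
#' image y, columns image x, third dimension R, G, B).
#'
#' @slot pixels numeric array `H x W x 3`, values in \[0, 1\].
#' @slot bitDepth integer, 8 or 16: the depth of the source raster.
#' @slot eye `"right"` or `"left"` laterality.
#' @slot subjectId opaque subject label.
#' @export
setClass("FundusImage",
  representation(pixels = "array", bitDepth = "integer", eye = "character",
                 subjectId = "character"))

setValidity("FundusImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1] < 128L || dim(p)[2] < 128L)
    return("image must be at least 128 x 128 pixels")
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    return("pixel values must lie in [0, 1]")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  if (!object@eye %in% c("right", "left"))
    return("eye must be 'right' or 'left'")
  TRUE
})

#' DiscGeometry: the delimited optic nerve head border
#'
#' Axis-aligned ellipse (circle when the semi-axes are equal) anchoring all
#' sector geometry, in pixel coordinates (x = column, y = row).
#'
#' @slot center numeric length-2 `(x, y)` center in pixels.
#' @slot radiusX,radiusY numeric semi-axes in pixels.
#' @slot eye `"right"` or `"left"`.
#' @export
setClass("DiscGeometry",
  representation(center = "numeric", radiusX = "numeric", radiusY = "numeric",
                 eye = "character"))

setValidity("DiscGeometry", function(object) {
  if (length(object@center) != 2L) return("center must be (x, y)")
  if (object@radiusX <= 0 || object@radiusY <= 0) return("radii must be > 0")
  if (pi * object@radiusX * object@radiusY < 500)
    return("disc area below the 500 px^2 minimum")
  if (!object@eye %in% c("right", "left"))
    return("eye must be 'right' or 'left'")
  TRUE
})

#' VesselMask: central retinal vessel pixels within the disc
#'
#' @slot mask logical matrix congruent with the source image, `TRUE` on
#'   vessel pixels inside the disc.
#' @slot vesselFraction numeric, vessel share of the disc interior area.
#' @slot lowConfidence logical, `TRUE` when the vessel fraction falls
#'   outside the accepted \[0.05, 0.60\] range.
#' @export
setClass("VesselMask",
  representation(mask = "matrix", vesselFraction = "numeric",
                 lowConfidence = "logical"))

setValidity("VesselMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

#' DiscRegions: the two-region partition of the disc interior
#'
#' The interior of the delimited disc split into central retinal vessels and
#' the remaining tissue: `tissue & vessels` is empty and `tissue | vessels`
#' is exactly the disc interior.
#'
#' @slot disc a [DiscGeometry-class].
#' @slot vessels,tissue logical matrices congruent with the source image.
#' @export
setClass("DiscRegions",
  representation(disc = "DiscGeometry", vessels = "matrix", tissue = "matrix"))

setValidity("DiscRegions", function(object) {
  if (!identical(dim(object@vessels), dim(object@tissue)))
    return("vessels and tissue rasters must be congruent")
  if (any(object@vessels & object@tissue))
    return("tissue and vessels must be disjoint")
  TRUE
})

#' QCReport: result of the preprocessing quality gate
#'
#' @slot passed logical; `TRUE` iff `reasons` is empty.
#' @slot meanLuminance mean over pixels of the per-pixel channel mean.
#' @slot saturatedFraction numeric length 3, per-channel fraction of
#'   saturated pixels.
#' @slot reasons character vector of failure codes.
#' @export
setClass("QCReport",
  representation(passed = "logical", meanLuminance = "numeric",
                 saturatedFraction = "numeric", reasons = "character"))

setValidity("QCReport", function(object) {
  if (object@passed != (length(object@reasons) == 0L))
    return("passed must be TRUE exactly when reasons is empty")
  if (length(object@saturatedFraction) != 3L)
    return("saturatedFraction must have one entry per channel")
  TRUE
})

#' LensCompensation: estimated crystalline-lens yellowing correction
#'
#' A yellowed (cataractous) lens attenuates blue light by a factor
#' `kappa` and green by `(1 + kappa) / 2`. The blue factor is estimated
#' from the blue:green ratio of the vessel pixels against the clear-lens
#' vessel calibration ratio; the green correction applied downstream is the
#' multiplicative inverse `greenScale = 2 / (1 + kappaHat)`.
#'
#' @slot kappaHat estimated blue-attenuation factor in (0, 1\].
#' @slot greenScale multiplicative correction applied to the green channel.
#' @slot flagged logical, `TRUE` when the estimate had to be clamped.
#' @export
setClass("LensCompensation",
  representation(kappaHat = "numeric", greenScale = "numeric",
                 flagged = "logical"))

setValidity("LensCompensation", function(object) {
  if (object@kappaHat <= 0 || object@kappaHat > 1)
    return("kappaHat must lie in (0, 1]")
  TRUE
})

#' HbMap: per-pixel hemoglobin percentage over the disc
#'
#' Tissue pixels carry the vessel-referenced Hb percentage in \[0, 120\]
#' (values above 100 are retained, not destroyed: tissue redder than the
#' vessel median is possible under noise); vessel pixels carry the defined
#' value 100; pixels outside the disc are `NA`.
#'
#' @slot values numeric matrix congruent with the source image.
#' @slot vesselReference named numeric `(r, g)` median vessel channels
#'   (green after lens compensation).
#' @slot regions the [DiscRegions-class] the map was computed on.
#' @slot valid logical; `FALSE` when the vessel reference is not
#'   red-dominant.
#' @export
setClass("HbMap",
  representation(values = "matrix", vesselReference = "numeric",
                 regions = "DiscRegions", valid = "logical"))

setValidity("HbMap", function(object) {
  v <- object@values
  tm <- object@regions@tissue
  if (!identical(dim(v), dim(tm))) return("values raster not congruent")
  tv <- v[tm]
  if (length(tv) && (min(tv, na.rm = TRUE) < 0 || max(tv, na.rm = TRUE) > 120))
    return("tissue Hb values must lie in [0, 120]")
  TRUE
})

#' SectorMap: the 24-sector papillary partition
#'
#' Per-pixel sector labels: 0 outside the disc, 1..24 inside. Labels are
#' wedge-major, ring-minor: `label = 3 * (wedge - 1) + ring` with wedges
#' 1..8 counted from the temporal horizontal meridian (clockwise for right
#' eyes, counterclockwise for left eyes, so indices are anatomically
#' aligned across eyes) and rings 1 = inner (rho <= 1/3), 2 = middle,
#' 3 = outer in normalized elliptical radius. The outer ring is therefore
#' exactly the multiples of 3.
#'
#' @slot labels integer matrix congruent with the image.
#' @slot geometry the [DiscGeometry-class] the map was built on.
#' @slot numbering convention tag.
#' @export
setClass("SectorMap",
  representation(labels = "matrix", geometry = "DiscGeometry",
                 numbering = "character"))

#' SectorProfile: mean and 24-sector Hb percentages for one subject
#'
#' @slot meanHb mean Hb percentage over all tissue pixels.
#' @slot sectorHb numeric length 24; `NA` for sectors with no tissue pixels.
#' @slot sectorCounts tissue-pixel count per sector.
#' @slot subjectId,eye subject metadata.
#' @slot frame `"anatomical"` (right-eye-equivalent indexing, the package
#'   default) or `"screen"` (native raster orientation).
#' @export
setClass("SectorProfile",
  representation(meanHb = "numeric", sectorHb = "numeric",
                 sectorCounts = "numeric", subjectId = "character",
                 eye = "character", frame = "character"))

setValidity("SectorProfile", function(object) {
  if (length(object@sectorHb) != 24L || length(object@sectorCounts) != 24L)
    return("profile must carry exactly 24 sectors")
  sv <- object@sectorHb[!is.na(object@sectorHb)]
  if (length(sv) && (min(sv) < 0 || max(sv) > 120))
    return("sector Hb values must lie in [0, 120]")
  if (!object@frame %in% c("anatomical", "screen"))
    return("frame must be 'anatomical' or 'screen'")
  TRUE
})

#' SubjectSpec: ground-truth description of one synthetic fundus
#'
#' All parameters of the forward optical model for one synthetic subject;
#' rendering is fully deterministic given the spec (including its seed).
#'
#' @slot subjectId,group,eye subject metadata.
#' @slot trueSectorHb numeric length 24, true per-sector Hb percentage in
#'   \[0, 100\].
#' @slot size numeric `(H, W)` canvas in pixels.
#' @slot center numeric `(x, y)` disc center.
#' @slot radiusX,radiusY disc semi-axes in pixels.
#' @slot nBranches number of vessel branches.
#' @slot vesselWidth vessel trunk width in pixels.
#' @slot illumAmplitude relative amplitude of the illumination gradient.
#' @slot kappa lens blue-attenuation factor in (0, 1\]; 1 = clear lens.
#' @slot noiseSd additive Gaussian sensor noise SD (normalized units).
#' @slot seed RNG seed for the render.
#' @export
setClass("SubjectSpec",
  representation(subjectId = "character", group = "character",
                 eye = "character", trueSectorHb = "numeric",
                 size = "numeric", center = "numeric", radiusX = "numeric",
                 radiusY = "numeric", nBranches = "numeric",
                 vesselWidth = "numeric", illumAmplitude = "numeric",
                 kappa = "numeric", noiseSd = "numeric", seed = "numeric"))

setValidity("SubjectSpec", function(object) {
  if (length(object@trueSectorHb) != 24L)
    return("trueSectorHb must have 24 entries")
  if (min(object@trueSectorHb) < 0 || max(object@trueSectorHb) > 100)
    return("trueSectorHb must lie in [0, 100]")
  if (object@kappa <= 0 || object@kappa > 1)
    return("kappa must lie in (0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' CohortParams: parameters of the synthetic cohort generator
#'
#' Defaults encode the packaged reference study conditions: group sizes
#' 155 Parkinson / 91 healthy, per-sector Hb means and SDs per group, RNFL
#' thickness means and SDs for the Cirrus and Spectralis field layouts, and
#' a Hoehn-Yahr severity distribution of mean 2.68, SD 0.82 truncated to
#' \[1, 5\] for the disease group.
#'
#' @slot nPd,nHealthy group sizes.
#' @slot hb data.frame with columns `sector`, `healthyMean`, `healthySd`,
#'   `pdMean`, `pdSd`.
#' @slot cirrus,spectralis data.frames with columns `parameter`,
#'   `healthyMean`, `healthySd`, `pdMean`, `pdSd`.
#' @slot hoehnYahr numeric `(mean, sd)` for the disease group.
#' @slot imageSize canvas side in pixels.
#' @slot discRadius nominal disc semi-axis in pixels.
#' @slot illumAmplitude,kappa,noiseSd forward-model nuisance parameters
#'   shared by all subjects.
#' @slot seed master seed; per-subject seeds are fanned out from it.
#' @export
setClass("CohortParams",
  representation(nPd = "numeric", nHealthy = "numeric", hb = "data.frame",
                 cirrus = "data.frame", spectralis = "data.frame",
                 hoehnYahr = "numeric", imageSize = "numeric",
                 discRadius = "numeric", illumAmplitude = "numeric",
                 kappa = "numeric", noiseSd = "numeric", seed = "numeric"))

#' SyntheticCohort: a drawn cohort with ground truth and render specs
#'
#' @slot truth data.frame with one row per subject: group, eye, true
#'   per-sector Hb, true mean Hb, RNFL fields, covariates.
#' @slot specs list of [SubjectSpec-class], one per subject.
#' @slot params the [CohortParams-class] used.
#' @export
setClass("SyntheticCohort",
  representation(truth = "data.frame", specs = "list",
                 params = "CohortParams"))
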