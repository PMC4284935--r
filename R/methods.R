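#' @rdname discHb-accessors
setMethod("fundusPixels", "FundusImage", function(x) x@pixels)

#' @rdname discHb-accessors
setMethod("eyeSide", "FundusImage", function(x) x@eye)

#' @rdname discHb-accessors
setMethod("eyeSide", "DiscGeometry", function(x) x@eye)

#' @rdname discHb-accessors
setMethod("eyeSide", "SectorProfile", function(x) x@eye)

#' @rdname discHb-accessors
setMethod("subjectID", "FundusImage", function(x) x@subjectId)

#' @rdname discHb-accessors
setMethod("subjectID", "SectorProfile", function(x) x@subjectId)

#' @rdname discHb-accessors
setMethod("discCenter", "DiscGeometry", function(x)
  setNames(x@center, c("x", "y")))

#' @rdname discHb-accessors
setMethod("discRadii", "DiscGeometry", function(x)
  c(x = x@radiusX, y = x@radiusY))

#' @rdname discHb-accessors
setMethod("vesselMask", "VesselMask", function(x) x@mask)

#' @rdname discHb-accessors
setMethod("vesselMask", "DiscRegions", function(x) x@vessels)

#' @rdname discHb-accessors
setMethod("tissueMask", "DiscRegions", function(x) x@tissue)

#' @rdname discHb-accessors
setMethod("hbValues", "HbMap", function(x) x@values)

#' @rdname discHb-accessors
setMethod("vesselReference", "HbMap", function(x) x@vesselReference)

#' @rdname discHb-accessors
setMethod("sectorLabels", "SectorMap", function(x) x@labels)

#' @rdname discHb-accessors
setMethod("meanHb", "SectorProfile", function(x) x@meanHb)

#' @rdname discHb-accessors
setMethod("sectorHb", "SectorProfile", function(x) x@sectorHb)

#' @rdname discHb-accessors
setMethod("sectorCounts", "SectorProfile", function(x) x@sectorCounts)

#' @rdname discHb-accessors
setMethod("qcPassed", "QCReport", function(x) x@passed)

#' @rdname discHb-accessors
setMethod("qcReasons", "QCReport", function(x) x@reasons)

#' @rdname discHb-accessors
setMethod("kappaHat", "LensCompensation", function(x) x@kappaHat)

#' @rdname discHb-accessors
setMethod("greenScale", "LensCompensation", function(x) x@greenScale)

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage '%s' (%s eye): %d x %d px, %d-bit source\n",
              object@subjectId, object@eye, d[2], d[1], object@bitDepth))
})

setMethod("show", "DiscGeometry", function(object) {
  cat(sprintf(
    "DiscGeometry (%s eye): center (%.1f, %.1f), semi-axes %.1f x %.1f px\n",
    object@eye, object@center[1], object@center[2],
    object@radiusX, object@radiusY))
})

setMethod("show", "VesselMask", function(object) {
  cat(sprintf("VesselMask: %d vessel px (%.1f%% of disc)%s\n",
              sum(object@mask), 100 * object@vesselFraction,
              if (object@lowConfidence) " [low confidence]" else ""))
})

setMethod("show", "DiscRegions", function(object) {
  cat(sprintf("DiscRegions: %d tissue px + %d vessel px = %d interior px\n",
              sum(object@tissue), sum(object@vessels),
              sum(object@tissue) + sum(object@vessels)))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %s (mean luminance %.3f; saturated %s)\n",
              if (object@passed) "PASS" else "FAIL",
              object@meanLuminance,
              paste(sprintf("%.3f", object@saturatedFraction),
                    collapse = "/")))
  if (!object@passed)
    cat("  reasons:", paste(object@reasons, collapse = ", "), "\n")
})

setMethod("show", "LensCompensation", function(object) {
  cat(sprintf("LensCompensation: kappaHat %.3f, greenScale %.3f%s\n",
              object@kappaHat, object@greenScale,
              if (object@flagged) " [flagged]" else ""))
})

setMethod("show", "HbMap", function(object) {
  tv <- object@values[object@regions@tissue]
  cat(sprintf(
    "HbMap: mean tissue Hb %.1f%% over %d px (vessel reference r=%.3f g=%.3f)%s\n",
    mean(tv, na.rm = TRUE), length(tv),
    object@vesselReference[["r"]], object@vesselReference[["g"]],
    if (object@valid) "" else " [invalid reference]"))
})

setMethod("show", "SectorMap", function(object) {
  cat(sprintf("SectorMap: %d labeled px, %d sectors, numbering '%s'\n",
              sum(object@labels > 0), length(setdiff(unique(
                as.vector(object@labels)), 0L)), object@numbering))
})

setMethod("show", "SectorProfile", function(object) {
  cat(sprintf("SectorProfile '%s' (%s eye, %s frame): mean Hb %.1f%%\n",
              object@subjectId, object@eye, object@frame, object@meanHb))
  v <- round(object@sectorHb, 1)
  cat("  sectors 1-24:", paste(v, collapse = " "), "\n")
})

setMethod("show", "SubjectSpec", function(object) {
  cat(sprintf(
    "SubjectSpec '%s' (%s, %s eye): %dx%d px, disc r=(%.0f,%.0f), kappa=%.2f, noise=%.3f, seed=%d\n",
    object@subjectId, object@group, object@eye, object@size[2],
    object@size[1], object@radiusX, object@radiusY, object@kappa,
    object@noiseSd, as.integer(object@seed)))
})

setMethod("show", "CohortParams", function(object) {
  cat(sprintf(
    "CohortParams: %d PD + %d healthy, %dx%d px, disc r~%.0f, kappa=%.2f, noise=%.3f, seed=%d\n",
    object@nPd, object@nHealthy, object@imageSize, object@imageSize,
    object@discRadius, object@kappa, object@noiseSd,
    as.integer(object@seed)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects (%d PD, %d healthy)\n",
              nrow(object@truth), sum(object@truth$group == "PD"),
              sum(object@truth$group == "healthy")))
})
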