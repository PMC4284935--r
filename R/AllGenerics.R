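#' @name discHb-accessors
#' @title Accessors for discHb classes
#' @description Slot accessors for the package's S4 containers. Use these
#'   rather than `@` access.
#' @param x an object of the documented class.
#' @return The slot value (see each accessor).
NULL

#' @rdname discHb-accessors
#' @export
setGeneric("fundusPixels", function(x) standardGeneric("fundusPixels"))

#' @rdname discHb-accessors
#' @export
setGeneric("eyeSide", function(x) standardGeneric("eyeSide"))

#' @rdname discHb-accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname discHb-accessors
#' @export
setGeneric("discCenter", function(x) standardGeneric("discCenter"))

#' @rdname discHb-accessors
#' @export
setGeneric("discRadii", function(x) standardGeneric("discRadii"))

#' @rdname discHb-accessors
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))

#' @rdname discHb-accessors
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))

#' @rdname discHb-accessors
#' @export
setGeneric("hbValues", function(x) standardGeneric("hbValues"))

#' @rdname discHb-accessors
#' @export
setGeneric("vesselReference", function(x) standardGeneric("vesselReference"))

#' @rdname discHb-accessors
#' @export
setGeneric("sectorLabels", function(x) standardGeneric("sectorLabels"))

#' @rdname discHb-accessors
#' @export
setGeneric("meanHb", function(x) standardGeneric("meanHb"))

#' @rdname discHb-accessors
#' @export
setGeneric("sectorHb", function(x) standardGeneric("sectorHb"))

#' @rdname discHb-accessors
#' @export
setGeneric("sectorCounts", function(x) standardGeneric("sectorCounts"))

#' @rdname discHb-accessors
#' @export
setGeneric("qcPassed", function(x) standardGeneric("qcPassed"))

#' @rdname discHb-accessors
#' @export
setGeneric("qcReasons", function(x) standardGeneric("qcReasons"))

#' @rdname discHb-accessors
#' @export
setGeneric("kappaHat", function(x) standardGeneric("kappaHat"))

#' @rdname discHb-accessors
#' @export
setGeneric("greenScale", function(x) standardGeneric("greenScale"))

#' Mirror a sector profile into the reference (right-eye) orientation
#'
#' @param p a [SectorProfile-class].
#' @return a [SectorProfile-class] in the anatomical frame.
#' @seealso [aggregateSectors()]
#' @export
setGeneric("mirrorProfile", function(p) standardGeneric("mirrorProfile"))
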