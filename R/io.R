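#' Construct a FundusImage from an in-memory array
#'
#' @param pixels numeric `H x W x 3` array with values in \[0, 1\].
#' @param bitDepth source bit depth, 8 or 16.
#' @param eye `"right"` or `"left"`.
#' @param subjectId opaque subject label.
#' @return a [FundusImage-class].
#' @export
FundusImage <- function(pixels, bitDepth = 8L, eye = "right",
                        subjectId = "anonymous") {
  new("FundusImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      eye = eye, subjectId = subjectId)
}

# PNG bit depth from the IHDR chunk (byte 25 of the file)
.pngBitDepth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop("unreadable PNG file: ", path)
  as.integer(hdr[25L])
}

#' Read a fundus photograph from disk
#'
#' Decodes an 8- or 16-bit RGB raster (PNG, TIFF or JPEG), normalizes
#' channels to \[0, 1\] and attaches metadata. No resampling or enhancement
#' is performed. Grayscale or paletted images are rejected; an alpha
#' channel, if present, is dropped with a warning.
#'
#' @param path file path.
#' @param eye laterality, `"right"` or `"left"`.
#' @param subjectId subject label; defaults to the file stem.
#' @return a [FundusImage-class].
#' @export
loadFundus <- function(path, eye = "right",
                       subjectId = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    px <- png::readPNG(path)
    depth <- .pngBitDepth(path)
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(px, "bits.per.sample")
    depth <- if (is.null(bps)) 8L else as.integer(bps)
    px <- array(as.vector(px), dim(px))  # drop TIFF metadata attributes
  } else if (ext %in% c("jpg", "jpeg")) {
    im <- EBImage::readImage(path)
    px <- im@.Data
    if (length(dim(px)) == 3L) px <- aperm(px, c(2L, 1L, 3L))
    depth <- 8L
  } else stop("unsupported image format: .", ext)
  if (length(dim(px)) < 3L)
    stop("non-RGB image (grayscale or paletted): ", path)
  if (dim(px)[3] == 4L) {
    warning("dropping alpha channel")
    px <- px[, , 1:3, drop = FALSE]
  }
  if (dim(px)[3] != 3L)
    stop("non-RGB image (", dim(px)[3], " channels): ", path)
  if (!depth %in% c(8L, 16L)) depth <- 8L
  FundusImage(.clamp(px, 0, 1), bitDepth = depth, eye = eye,
              subjectId = subjectId)
}

#' Write a fundus image to disk
#'
#' 8-bit output goes to PNG (or TIFF by extension); 16-bit output requires
#' TIFF. Values are quantized to the target depth.
#'
#' @param img a [FundusImage-class].
#' @param path destination; extension selects the container.
#' @param bitDepth 8 or 16; defaults to the image's recorded depth.
#' @return `path`, invisibly.
#' @export
writeFundus <- function(img, path, bitDepth = img@bitDepth) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    if (bitDepth != 8L)
      stop("16-bit output is only supported for TIFF; use a .tif path")
    png::writePNG(img@pixels, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img@pixels, path, bits.per.sample = as.integer(bitDepth))
  } else stop("unsupported output format: .", ext)
  invisible(path)
}

#' Read a disc-annotation sidecar
#'
#' JSON sidecar with fields `subject_id`, `eye` and an optional
#' `disc_seed` `(x, y)` used to window [segmentDisc()], or a full geometry
#' (`center`, `radius_x`, `radius_y`) that bypasses it.
#'
#' @param path JSON file path.
#' @return list with `subjectId`, `eye`, `discSeed` (or `NULL`) and
#'   `geometry` (a [DiscGeometry-class] or `NULL`).
#' @export
readDiscAnnotation <- function(path) {
  a <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- NULL
  if (!is.null(a$center) && !is.null(a$radius_x) && !is.null(a$radius_y))
    geom <- new("DiscGeometry", center = as.numeric(a$center),
                radiusX = a$radius_x, radiusY = a$radius_y,
                eye = if (is.null(a$eye)) "right" else a$eye)
  list(subjectId = if (is.null(a$subject_id)) NA_character_ else a$subject_id,
       eye = if (is.null(a$eye)) NA_character_ else a$eye,
       discSeed = if (is.null(a$disc_seed)) NULL else as.numeric(a$disc_seed),
       geometry = geom)
}

#' Quality-gate a fundus photograph
#'
#' Computes the mean luminance (mean over pixels of the per-pixel channel
#' mean) and the per-channel fraction of saturated pixels (value at or
#' above `1 - eps`). The image passes when the mean luminance lies within
#' `[lumLo, lumHi]` and every saturated fraction is at most `satMax`.
#' A report is always returned; nothing is modified or enhanced, because
#' any color "improvement" would corrupt the downstream colorimetry.
#'
#' @param img a [FundusImage-class].
#' @param lumLo,lumHi luminance gates (defaults 0.15, 0.85).
#' @param satMax maximal tolerated saturated fraction per channel
#'   (default 0.01).
#' @param eps saturation margin (default 1/255, one 8-bit step).
#' @return a [QCReport-class].
#' @examples
#' img <- renderFundus(subjectSpec(seed = 7))$image
#' qcCheck(img)
#' @export
qcCheck <- function(img, lumLo = 0.15, lumHi = 0.85, satMax = 0.01,
                    eps = 1 / 255) {
  px <- img@pixels
  lum <- mean(px)
  satFrac <- vapply(1:3, function(ch) mean(px[, , ch] >= 1 - eps),
                    numeric(1))
  reasons <- character(0)
  if (lum < lumLo) reasons <- c(reasons, "underexposed")
  if (lum > lumHi) reasons <- c(reasons, "overexposed")
  sat <- c("saturated-red", "saturated-green", "saturated-blue")[
    satFrac > satMax]
  reasons <- c(reasons, sat)
  new("QCReport", passed = length(reasons) == 0L, meanLuminance = lum,
      saturatedFraction = satFrac, reasons = reasons)
}
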