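#' Run the full single-image Hb analysis
#'
#' Convenience wrapper chaining the pipeline stages: quality gate, disc
#' delimitation (or an externally supplied geometry), vessel segmentation,
#' lens compensation, per-pixel Hb estimation, 24-sector aggregation.
#'
#' @param img a [FundusImage-class].
#' @param discSeed optional `(x, y)` manual disc hint for [segmentDisc()].
#' @param geometry optional [DiscGeometry-class] bypassing segmentation.
#' @param lensComp apply lens compensation (default `TRUE`; silently
#'   skipped when fewer than 50 vessel pixels are available).
#' @param vesselFrac median-green fraction for [segmentVessels()].
#' @param stopOnQC error out when the QC gate fails (default `FALSE`:
#'   the report is attached and analysis proceeds).
#' @return list with components `qc`, `disc`, `vessels`, `regions`,
#'   `lens` (or `NULL`), `hb`, `sectorMap`, `profile`.
#' @examples
#' r <- renderFundus(subjectSpec(seed = 5))
#' fit <- analyzeFundus(r$image)
#' fit$profile
#' @export
analyzeFundus <- function(img, discSeed = NULL, geometry = NULL,
                          lensComp = TRUE, vesselFrac = 0.55,
                          stopOnQC = FALSE) {
  qc <- qcCheck(img)
  if (!qc@passed && stopOnQC)
    stop("image failed QC: ", paste(qc@reasons, collapse = ", "))
  disc <- if (!is.null(geometry)) geometry else
    segmentDisc(img, seed = discSeed)
  vm <- segmentVessels(img, disc, frac = vesselFrac)
  regions <- makeRegions(disc, vm)
  comp <- if (lensComp && sum(vm@mask) >= 50)
    estimateLensCompensation(img, regions) else NULL
  hb <- estimateHbMap(img, regions, comp)
  smap <- buildSectorMap(disc, dim(vm@mask))
  prof <- aggregateSectors(hb, smap)
  prof@subjectId <- img@subjectId
  list(qc = qc, disc = disc, vessels = vm, regions = regions, lens = comp,
       hb = hb, sectorMap = smap, profile = prof)
}

#' Analyze every subject of a synthetic cohort
#'
#' Renders each subject's fundus image, runs [analyzeFundus()] on it and
#' collects the estimated sector profiles into a cohort table alongside
#' the generator's ground truth, RNFL fields and covariates. Images are
#' rendered and discarded one at a time.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param lensComp,vesselFrac passed to [analyzeFundus()].
#' @param verbose print one line per subject.
#' @return the cohort's truth data.frame augmented with the estimated
#'   `mean_hb` and `hb_1` .. `hb_24` columns.
#' @export
analyzeCohort <- function(cohort, lensComp = TRUE, vesselFrac = 0.55,
                          verbose = FALSE) {
  n <- length(cohort@specs)
  est <- matrix(NA_real_, n, 25,
                dimnames = list(NULL, c("mean_hb", paste0("hb_", 1:24))))
  for (i in seq_len(n)) {
    sp <- cohort@specs[[i]]
    r <- renderFundus(sp)
    fit <- analyzeFundus(r$image, lensComp = lensComp,
                         vesselFrac = vesselFrac)
    est[i, ] <- c(meanHb(fit$profile), sectorHb(fit$profile))
    if (verbose)
      message(sprintf("%s: mean Hb %.1f%%", sp@subjectId, est[i, 1]))
  }
  cbind(cohort@truth, as.data.frame(est))
}
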