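# internal helpers shared across modules

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# evaluate `code` under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# pixel-center coordinate grids for an H x W raster: x = column, y = row
.coordGrids <- function(dm) {
  H <- dm[1]; W <- dm[2]
  list(x = matrix(seq_len(W), H, W, byrow = TRUE),
       y = matrix(seq_len(H), H, W))
}

# normalized elliptical coordinates relative to a DiscGeometry
.ellipseNorm <- function(geom, dm) {
  g <- .coordGrids(dm)
  list(dx = (g$x - geom@center[1]) / geom@radiusX,
       dy = (g$y - geom@center[2]) / geom@radiusY)
}

# disc interior mask (normalized elliptical radius <= 1)
.interiorMask <- function(geom, dm) {
  e <- .ellipseNorm(geom, dm)
  e$dx^2 + e$dy^2 <= 1
}

.checkInsideImage <- function(geom, dm) {
  cx <- geom@center[1]; cy <- geom@center[2]
  ok <- cx - geom@radiusX >= 1 && cx + geom@radiusX <= dm[2] &&
        cy - geom@radiusY >= 1 && cy + geom@radiusY <= dm[1]
  if (!ok) stop("disc ellipse is clipped by the image border")
  invisible(TRUE)
}

# largest connected component of a logical matrix (8-connectivity),
# NULL when empty
.largestComponent <- function(m) {
  if (!any(m)) return(NULL)
  lab <- EBImage::bwlabel(m + 0)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# analytic area weights of the 24 sectors: rings at 1/3 and 2/3 of the
# radius split the disc 1/9 : 3/9 : 5/9, each ring into 8 equal wedges
.sectorAreaWeights <- function() {
  ring <- rep(c(1, 3, 5) / 9 / 8, times = 8)
  ring
}
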