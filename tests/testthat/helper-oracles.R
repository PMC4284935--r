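# Independent brute-force oracles. These deliberately re-derive quantities
# with naive per-pixel loops / textbook formulas, never by calling the code
# paths they check.

naiveQcStats <- function(px, eps = 1 / 255) {
  H <- dim(px)[1]; W <- dim(px)[2]
  lumSum <- 0
  sat <- c(0, 0, 0)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    v <- px[y, x, ]
    lumSum <- lumSum + mean(v)
    sat <- sat + (v >= 1 - eps)
  }
  list(meanLuminance = lumSum / (H * W), saturatedFraction = sat / (H * W))
}

naiveSectorStats <- function(values, labels, tissue) {
  sums <- numeric(24); counts <- integer(24)
  H <- nrow(values); W <- ncol(values)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (tissue[y, x]) {
      s <- labels[y, x]
      sums[s] <- sums[s] + values[y, x]
      counts[s] <- counts[s] + 1L
    }
  }
  list(means = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
       counts = counts)
}

# per-pixel polar sector label, independently of the vectorized builder
naiveSectorLabel <- function(x, y, cx, cy, rx, ry, eye) {
  dx <- (x - cx) / rx
  dy <- (y - cy) / ry
  rho <- sqrt(dx^2 + dy^2)
  if (rho > 1) return(0L)
  sx <- if (eye == "right") -1 else 1
  phi <- atan2(-dy, sx * dx) %% (2 * pi)
  wedge <- min(8L, 1L + floor(phi / (pi / 4)))
  ring <- 1L + (rho > 1 / 3) + (rho > 2 / 3)
  as.integer(3 * (wedge - 1) + ring)
}

# textbook pooled-variance two-sample t
pooledT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, p = 2 * pt(-abs(tstat), n1 + n2 - 2))
}

naivePearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

diceOverlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# compact render used throughout the suite (fast; 192 px canvas)
smallSpec <- function(seed = 1, ...) subjectSpec(size = 192, seed = seed, ...)
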