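#' Normality gate for a sample
#'
#' Lilliefors-style one-sample Kolmogorov-Smirnov test against a normal
#' distribution with the sample's own mean and SD. The gate is advisory:
#' it is logged alongside the comparison tables, and the pipeline proceeds
#' with t tests either way (switching tests silently would change the
#' analysis contract).
#'
#' @param values numeric sample, `n >= 5`.
#' @param alpha gate level (default 0.05).
#' @return list with `normal` (logical), `statistic`, `p.value` and `n`.
#'   A zero-variance sample is degenerate and reported non-normal with
#'   `p.value = 0`.
#' @export
normalityGate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 5) stop("normality gate needs at least 5 observations; got ", n)
  if (sd(values) == 0)
    return(list(normal = FALSE, statistic = NA_real_, p.value = 0, n = n))
  kt <- nortest::lillie.test(values)
  list(normal = kt$p.value >= alpha,
       statistic = unname(kt$statistic), p.value = kt$p.value, n = n)
}

#' Bonferroni-corrected significance level
#'
#' @param baseAlpha family-wise level in (0, 1).
#' @param m number of comparisons in the family, `>= 1`.
#' @return `baseAlpha / m`. With the packaged measurement families this
#'   reproduces the usual printed thresholds: 0.05/25 = 0.002 for the Hb
#'   family (mean + 24 sectors), 0.05/17 for the Cirrus RNFL family
#'   (mean + 4 quadrants + 12 clock hours, approximately 0.003) and 0.05/9
#'   for the Spectralis family (approximately 0.006).
#' @export
bonferroniAlpha <- function(baseAlpha, m) {
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a positive comparison count")
  if (baseAlpha <= 0 || baseAlpha >= 1)
    stop("baseAlpha must lie in (0, 1)")
  baseAlpha / m
}

#' Compare two groups variable by variable
#'
#' Two-sided Student's t test per variable, pooled variance by default
#' (the literal named test; Welch is available behind `welch = TRUE` since
#' group SDs can differ markedly). Missing values are dropped per variable
#' (complete-case). The family-corrected level is
#' `bonferroniAlpha(baseAlpha, length(variables))`.
#'
#' @param cohort data.frame with a `group` column and the listed variables.
#' @param variables character vector of column names (the comparison
#'   family).
#' @param baseAlpha family-wise significance level (default 0.05).
#' @param groups length-2 character: reference group first; the reported
#'   difference is `mean(groups[1]) - mean(groups[2])`.
#' @param welch use the Welch (unpooled) variant.
#' @return data.frame with one row per variable, in input order: `variable`,
#'   `n1`, `n2`, `mean1`, `sd1`, `mean2`, `sd2`, `difference`, `t`, `p`,
#'   `alphaCorrected`, `significant`, `degenerate`. Zero pooled variance
#'   with equal means yields `t = 0, p = 1`; with unequal means the row is
#'   flagged degenerate.
#' @export
compareGroups <- function(cohort, variables, baseAlpha = 0.05,
                          groups = c("healthy", "PD"), welch = FALSE) {
  stopifnot("group" %in% names(cohort), length(groups) == 2L)
  alphaC <- bonferroniAlpha(baseAlpha, length(variables))
  rows <- lapply(variables, function(v) {
    x1 <- cohort[[v]][cohort$group == groups[1]]
    x2 <- cohort[[v]][cohort$group == groups[2]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2)
      stop("variable '", v, "' needs >= 2 observations per group")
    m1 <- mean(x1); m2 <- mean(x2)
    s1 <- sd(x1); s2 <- sd(x2)
    degen <- FALSE
    if (s1 == 0 && s2 == 0) {
      if (m1 == m2) { tstat <- 0; pval <- 1 }
      else { tstat <- NA_real_; pval <- NA_real_; degen <- TRUE }
    } else {
      tt <- t.test(x1, x2, var.equal = !welch)
      tstat <- unname(tt$statistic); pval <- tt$p.value
    }
    data.frame(variable = v, n1 = length(x1), n2 = length(x2),
               mean1 = m1, sd1 = s1, mean2 = m2, sd2 = s2,
               difference = m1 - m2, t = tstat, p = pval,
               alphaCorrected = alphaC,
               significant = !is.na(pval) && pval < alphaC,
               degenerate = degen)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlations between two variable families
#'
#' @param cohort data.frame holding all named columns.
#' @param left,right character vectors of column names (e.g. Hb sectors on
#'   the left, RNFL parameters on the right).
#' @return data.frame of all pairs: `left`, `right`, `r`, `p`, `n`.
#'   Pairwise-complete observations; pairs with fewer than 3 complete
#'   observations or a zero-variance column return `NA` with a warning.
#' @export
correlateVariables <- function(cohort, left, right) {
  grid <- expand.grid(left = left, right = right,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- cohort[[grid$left[i]]]
    y <- cohort[[grid$right[i]]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warning("undefined correlation for ", grid$left[i], " ~ ",
              grid$right[i], " (n or variance insufficient)")
      return(data.frame(left = grid$left[i], right = grid$right[i],
                        r = NA_real_, p = NA_real_, n = n))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(left = grid$left[i], right = grid$right[i],
               r = unname(ct$estimate), p = ct$p.value, n = n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Format a comparison table for reporting
#'
#' Renders the rows of [compareGroups()] in the conventional clinical
#' layout: variable, reference group "mean (SD)", comparison group
#' "mean (SD)", P, significance flag.
#'
#' @param rows output of [compareGroups()].
#' @param groupNames display names of the two groups.
#' @param digits digits for means/SDs (default 2) .
#' @return data.frame of formatted character columns plus the logical
#'   `significant` column.
#' @export
formatComparison <- function(rows, groupNames = c("Healthy", "PD"),
                             digits = 2) {
  fm <- function(m, s) sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                               m, s)
  out <- data.frame(variable = rows$variable,
                    g1 = fm(rows$mean1, rows$sd1),
                    g2 = fm(rows$mean2, rows$sd2),
                    P = ifelse(rows$p < 0.001, "<0.001",
                               sprintf("%.3f", rows$p)),
                    significant = rows$significant)
  names(out)[2:3] <- groupNames
  out
}

#' Write comparison rows to CSV (full precision, round-trippable)
#'
#' @param rows output of [compareGroups()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeComparisonCSV <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Render comparison rows as a Markdown table
#'
#' @param rows output of [compareGroups()].
#' @param groupNames display names of the two groups.
#' @return character vector of Markdown lines, including a footnote with
#'   the family-corrected level.
#' @export
comparisonMarkdown <- function(rows, groupNames = c("Healthy", "PD")) {
  ft <- formatComparison(rows, groupNames)
  header <- sprintf("| Variable | %s | %s | P | |", groupNames[1],
                    groupNames[2])
  sep <- "|---|---|---|---|---|"
  body <- sprintf("| %s | %s | %s | %s | %s |", ft$variable, ft[[2]],
                  ft[[3]], ft$P, ifelse(ft$significant, "*", ""))
  foot <- sprintf(
    "*Significant at the Bonferroni-corrected level P < %.4g (family of %d).",
    rows$alphaCorrected[1], nrow(rows))
  c(header, sep, body, "", foot)
}
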