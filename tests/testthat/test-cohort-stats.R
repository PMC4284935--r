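test_that("the KS normality gate separates normal from skewed samples", {
  set.seed(101)
  g1 <- normalityGate(rnorm(500))
  expect_true(g1$normal)
  set.seed(102)
  g2 <- normalityGate(rexp(500))
  expect_false(g2$normal)
  expect_lt(g2$p.value, 0.001)
  # zero-variance degenerate and insufficient samples
  expect_false(normalityGate(rep(3.2, 50))$normal)
  expect_error(normalityGate(c(1, 2, 3)), "at least 5")
})

test_that("Bonferroni arithmetic reproduces the family thresholds", {
  expect_identical(bonferroniAlpha(0.05, 25), 0.002)
  expect_identical(bonferroniAlpha(0.05, 1), 0.05)
  expect_equal(round(bonferroniAlpha(0.05, 17), 3), 0.003)
  expect_equal(round(bonferroniAlpha(0.05, 9), 3), 0.006)
  expect_error(bonferroniAlpha(0.05, 0), "positive")
  m <- 1:50
  expect_true(all(diff(bonferroniAlpha(0.05, 1) / m) < 0))
})

test_that("group comparison equals the textbook pooled-t oracle", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rnorm(sample(5:50, 1), mean = runif(1, 40, 80), sd = runif(1, 5, 20))
    y <- rnorm(sample(5:50, 1), mean = runif(1, 40, 80), sd = runif(1, 5, 20))
    cohort <- data.frame(group = rep(c("healthy", "PD"),
                                     c(length(x), length(y))),
                         v = c(x, y))
    row <- compareGroups(cohort, "v")
    o <- pooledT(x, y)
    expect_equal(row$t, o$t, tolerance = 1e-10)
    expect_equal(row$p, o$p, tolerance = 1e-10)
    expect_equal(row$difference, mean(x) - mean(y), tolerance = 1e-12)
  }
})

test_that("summary-matched synthetic groups separate at the family level", {
  set.seed(13)
  x <- rnorm(91, 67, 11)   # healthy mean Hb parameters
  y <- rnorm(155, 58, 19)  # disease group
  cohort <- data.frame(group = rep(c("healthy", "PD"), c(91, 155)),
                       mean_hb = c(x, y))
  fam <- compareGroups(cohort, rep("mean_hb", 1), baseAlpha = 0.05)
  # compare against the 25-comparison Hb family level explicitly
  o <- pooledT(x, y)
  expect_lt(o$p, bonferroniAlpha(0.05, 25))
  expect_equal(fam$t, o$t, tolerance = 1e-10)
  # single-variable family leaves alpha uncorrected
  expect_equal(fam$alphaCorrected, 0.05)
})

test_that("degenerate comparisons are handled explicitly", {
  same <- data.frame(group = rep(c("healthy", "PD"), each = 4),
                     v = rep(c(1, 2, 3, 4), 2))
  r1 <- compareGroups(same, "v")
  expect_equal(r1$t, 0)
  expect_equal(r1$p, 1)
  expect_false(r1$significant)

  const <- data.frame(group = rep(c("healthy", "PD"), each = 4),
                      a = rep(5, 8), b = rep(c(5, 7), each = 4))
  r2 <- compareGroups(const, c("a", "b"))
  expect_equal(r2$t[1], 0); expect_equal(r2$p[1], 1)
  expect_true(r2$degenerate[2])
  expect_true(is.na(r2$p[2]))
})

test_that("under the null the family-wise error rate is calibrated", {
  set.seed(77)
  hits <- 0L
  nrep <- 500
  for (i in seq_len(nrep)) {
    dat <- as.data.frame(matrix(rnorm(40 * 25), 40, 25))
    dat$group <- rep(c("healthy", "PD"), each = 20)
    rows <- compareGroups(dat, paste0("V", 1:25))
    hits <- hits + any(rows$significant)
  }
  expect_gt(hits, nrep * 0.05 * 0.5)
  expect_lt(hits, nrep * 0.05 * 1.5)
})

test_that("Pearson correlations hit exact anchors and match the oracle", {
  x <- seq(1, 10, by = 0.5)
  d <- data.frame(x = x, lin = 2 * x + 1, neg = -x, const = rep(1, length(x)))
  expect_equal(correlateVariables(d, "x", "lin")$r, 1)
  expect_equal(correlateVariables(d, "x", "neg")$r, -1)
  expect_equal(correlateVariables(d, "x", "x")$r, 1)
  expect_warning(rz <- correlateVariables(d, "x", "const"), "undefined")
  expect_true(is.na(rz$r))

  set.seed(21)
  for (rep in 1:10) {
    a <- rnorm(30); b <- rnorm(30)
    dd <- data.frame(a = a, b = b)
    expect_equal(correlateVariables(dd, "a", "b")$r, naivePearson(a, b),
                 tolerance = 1e-10)
  }
})

test_that("independent columns show small r and uniform-ish p values", {
  set.seed(31)
  ps <- rs <- numeric(200)
  for (i in 1:200) {
    dd <- data.frame(a = rnorm(246), b = rnorm(246))
    res <- correlateVariables(dd, "a", "b")
    ps[i] <- res$p; rs[i] <- res$r
  }
  expect_lt(mean(abs(rs)), 0.08)
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.01); expect_lt(frac, 0.10)
})

test_that("report tables format, serialize and round-trip", {
  set.seed(41)
  vars <- c("mean_hb", paste0("hb_", 1:24))
  dat <- as.data.frame(setNames(lapply(vars, function(v)
    c(rnorm(20, 67, 11), rnorm(30, 58, 19))), vars))
  dat$group <- rep(c("healthy", "PD"), c(20, 30))
  rows <- compareGroups(dat, vars)
  expect_equal(nrow(rows), 25)

  ft <- formatComparison(rows)
  expect_identical(names(ft)[2:3], c("Healthy", "PD"))
  expect_match(ft$Healthy[1], "^\\d+\\.\\d+ \\(\\d+\\.\\d+\\)$")

  md <- comparisonMarkdown(rows)
  expect_length(grep("^\\| ", md), 26)  # header + 25 data lines
  expect_match(md[length(md)], "0.002")

  f <- tempfile(fileext = ".csv")
  writeComparisonCSV(rows, f)
  back <- read.csv(f)
  expect_equal(back$t, rows$t, tolerance = 1e-12)
  expect_equal(back$mean1, rows$mean1, tolerance = 1e-12)
  expect_equal(back$significant, rows$significant)

  # single-row report
  one <- compareGroups(dat, "mean_hb")
  expect_equal(nrow(formatComparison(one)), 1)
})
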