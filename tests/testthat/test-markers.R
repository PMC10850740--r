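# small measurement matrix built in code: 2 subjects x 2 analytes x 3 tps
smallMatrix <- function(llod = numeric(0)) {
  arr <- array(NA_real_, dim = c(2, 2, 3),
               dimnames = list(subject = c("S1", "S2"),
                               analyte = c("CD8", "IFNg"),
                               timepoint = c("Pre", "PI", "PC")))
  arr["S1", "CD8", ] <- c(20, 20, 40)
  arr["S2", "CD8", ] <- c(10, 100, 5)
  arr["S1", "IFNg", ] <- c(5, 50, 0.05)
  arr["S2", "IFNg", ] <- c(2, 2, NA)
  AnalyteMatrix(arr, llod = llod)
}

test_that("log fold-change is log(value / baseline) with an exact zero baseline column", {
  lfc <- logFoldChange(smallMatrix(), baseline = "Pre", base = 10)
  v <- analyteValues(lfc)
  expect_identical(unname(v[, , "Pre"]), matrix(0, 2, 2))
  expect_equal(v["S2", "CD8", "PI"], 1)          # 10 -> 100, base 10
  expect_equal(v["S1", "CD8", "PI"], 0)          # unchanged
  expect_equal(v["S1", "CD8", "PC"], log10(2))
  expect_true(is.na(v["S2", "IFNg", "PC"]))      # missing propagates

  lfc2 <- logFoldChange(smallMatrix(), baseline = "Pre", base = 2)
  expect_equal(analyteValues(lfc2)["S1", "CD8", "PC"], 1)

  # exponentiation recovers the ratio wherever both values are positive
  m <- smallMatrix()
  v10 <- analyteValues(logFoldChange(m, base = 10))
  raw <- analyteValues(m)
  ratio <- sweep(raw, c(1, 2), raw[, , "Pre"], "/")
  ok <- !is.na(v10)
  expect_equal((10^v10)[ok], ratio[ok], tolerance = 1e-9)
})

test_that("below-LLOD values are floored before the transform and counted", {
  lfc <- logFoldChange(smallMatrix(llod = c(IFNg = 0.5)), baseline = "Pre")
  expect_identical(lfc@flooredCount, 1L)
  expect_equal(analyteValues(lfc)["S1", "IFNg", "PC"], log10(0.5 / 5))

  # zero with no declared LLOD yields missing, never -Inf
  m <- smallMatrix()
  lfcNoFloor <- logFoldChange(m, baseline = "Pre")
  expect_true(all(is.finite(analyteValues(lfcNoFloor)) |
                  is.na(analyteValues(lfcNoFloor))))
})

test_that("cohort mean recovers simulated log fold-changes", {
  # single subject: means are that subject's values
  lfc <- logFoldChange(smallMatrix(), baseline = "Pre")
  one <- AnalyteMatrix(analyteValues(smallMatrix())[1, , , drop = FALSE])
  mOne <- cohortMeanLogFC(logFoldChange(one, baseline = "Pre"))
  expect_equal(unname(mOne$mean[, "PI"]),
               unname(analyteValues(lfc)["S1", , "PI"]))

  # symmetric +1/-1 pair averages to zero
  arr <- array(c(1, 1, 10, 10, 10, 0.1), dim = c(2, 1, 3),
               dimnames = list(subject = c("A", "B"), analyte = "X",
                               timepoint = c("Pre", "PI", "PC")))
  m2 <- cohortMeanLogFC(logFoldChange(AnalyteMatrix(arr), baseline = "Pre"))
  expect_equal(unname(m2$mean["X", "PC"]), 0)
  expect_equal(unname(m2$n["X", "PC"]), 2)

  # 5 subjects, true log10-FC 0.5 at PI: cohort mean within 2 SE of truth
  spec <- data.frame(analyte = "X", baselineMeanlog = log(10),
                     baselineSdlog = 0.4, noiseSdlog = 0.15, llod = NA,
                     effect.Pre = 1, effect.PI = 10^0.5, effect.PC = 1,
                     effect.PS = 1, stringsAsFactors = FALSE)
  cfg <- simulationConfig(nSubjects = 5L, analyteSpec = spec, seed = 41)
  sim <- simulateAnalytes(cfg)
  lfcS <- logFoldChange(sim$matrix, baseline = "Pre", base = 10)
  perSubj <- analyteValues(lfcS)[, "X", "PI"]
  se <- sd(perSubj) / sqrt(length(perSubj))
  expect_lt(abs(mean(perSubj) - 0.5), 2 * se + 1e-12)
})

test_that("cell ratios divide elementwise and never emit infinities", {
  m <- smallMatrix()
  r <- cellRatio(m, "CD8", "IFNg")
  expect_equal(r["S1", "Pre"], 4)
  expect_equal(r["S2", "PI"], 50)
  expect_true(is.na(r["S2", "PC"]))  # missing denominator

  arr <- analyteValues(m)
  arr["S1", "IFNg", "PI"] <- 0
  m0 <- AnalyteMatrix(arr)
  expect_warning(r0 <- cellRatio(m0, "CD8", "IFNg"), "zero denominator")
  expect_true(is.na(r0["S1", "PI"]))
  expect_true(all(is.finite(r0) | is.na(r0)))

  expect_equal(unname(cellRatio(m, "CD8", "CD8")["S1", ]), rep(1, 3))
  expect_error(cellRatio(m, "CD8", "Treg"), "Treg")
})

test_that("paired t matches the closed form and handles degenerate input", {
  # identical columns: t = 0, p = 1
  arr <- array(rep(c(3, 7), 3), dim = c(2, 1, 3),
               dimnames = list(subject = c("A", "B"), analyte = "X",
                               timepoint = c("Pre", "PI", "PC")))
  res <- pairedT(AnalyteMatrix(arr), "Pre", "PI")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # constant nonzero differences: degenerate, p missing rather than 0
  arr2 <- array(c(1, 2, 3, 4, 2, 3, 4, 5), dim = c(4, 1, 2),
                dimnames = list(subject = paste0("S", 1:4), analyte = "X",
                                timepoint = c("Pre", "PI")))
  res2 <- pairedT(AnalyteMatrix(arr2), "Pre", "PI")
  expect_true(res2$degenerate)
  expect_true(is.na(res2$p))

  # textbook hand computation: d = {2.1, 1.8, 2.4, 2.0, 1.7}
  d <- c(2.1, 1.8, 2.4, 2.0, 1.7)
  arr3 <- array(c(rep(0, 5), d), dim = c(5, 1, 2),
                dimnames = list(subject = paste0("S", 1:5), analyte = "X",
                                timepoint = c("Pre", "PI")))
  res3 <- pairedT(AnalyteMatrix(arr3), "Pre", "PI")
  tHand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res3$t, tHand, tolerance = 1e-12)
  expect_equal(res3$t, 16.329931619, tolerance = 1e-6)
  expect_equal(res3$p, 2 * pt(-tHand, df = 4), tolerance = 1e-12)
  expect_equal(res3$n, 5L)

  # fewer than 2 complete pairs: missing result with n reported
  arr4 <- arr3
  arr4[2:5, 1, 2] <- NA
  res4 <- pairedT(AnalyteMatrix(arr4), "Pre", "PI")
  expect_true(is.na(res4$p))
  expect_equal(res4$n, 1L)
})

test_that("paired t is antisymmetric in its labels", {
  set.seed(7)
  arr <- array(rlnorm(24), dim = c(6, 2, 2),
               dimnames = list(subject = paste0("S", 1:6),
                               analyte = c("X", "Y"),
                               timepoint = c("Pre", "PC")))
  fwd <- pairedT(AnalyteMatrix(arr), "Pre", "PC")
  rev <- pairedT(AnalyteMatrix(arr), "PC", "Pre")
  expect_equal(rev$t, -fwd$t, tolerance = 1e-12)
  expect_equal(rev$p, fwd$p, tolerance = 1e-12)
})

test_that("null paired t rejects at close to the nominal rate", {
  spec <- data.frame(analyte = "X", baselineMeanlog = 0,
                     baselineSdlog = 0.4, noiseSdlog = 0.25, llod = NA,
                     effect.Pre = 1, effect.PI = 1,
                     stringsAsFactors = FALSE)
  rejections <- vapply(1:300, function(i) {
    cfg <- simulationConfig(depth = c(Pre = 10, PI = 10), nSubjects = 8L,
                            expansionSpec = data.frame(),
                            analyteSpec = spec, seed = 5000 + i)
    sim <- simulateAnalytes(cfg)
    pairedT(sim$matrix, "Pre", "PI")$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("zero-noise simulated analytes give log-FC exactly log(true effect)", {
  spec <- data.frame(analyte = c("A", "B"), baselineMeanlog = c(0, 1),
                     baselineSdlog = c(0.3, 0.3), noiseSdlog = c(0, 0),
                     llod = NA,
                     effect.Pre = 1, effect.PI = c(2, 0.5),
                     effect.PC = c(10, 1), stringsAsFactors = FALSE)
  cfg <- simulationConfig(depth = c(Pre = 10, PI = 10, PC = 10),
                          expansionSpec = data.frame(),
                          nSubjects = 4L, analyteSpec = spec, seed = 43)
  sim <- simulateAnalytes(cfg)
  lfc <- analyteValues(logFoldChange(sim$matrix, baseline = "Pre",
                                     base = 10))
  for (an in c("A", "B")) for (tp in c("PI", "PC"))
    expect_equal(unname(lfc[, an, tp]),
                 rep(log10(sim$truth[an, tp]), 4), tolerance = 1e-12)
})
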