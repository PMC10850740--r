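test_that("Fisher exact p-value closed cases", {
  expect_equal(fisherExactP(5, 95, 5, 95), 1)
  expect_equal(fisherExactP(0, 100, 0, 100), 1)
  expect_equal(fisherExactP(10, 9990, 40, 9960),
               bruteFisher(10, 9990, 40, 9960), tolerance = 1e-12)
  expect_error(fisherExactP(-1, 5, 2, 3), "non-negative")
  expect_error(fisherExactP(0, 0, 2, 3), "degenerate")
})

test_that("Fisher p matches brute-force enumeration and stats::fisher.test", {
  set.seed(13)
  for (rep in 1:60) {
    m <- sample(1:200, 1); n <- sample(1:200, 1)
    a <- sample(0:m, 1); c <- sample(0:n, 1)
    p <- fisherExactP(a, m - a, c, n - c)
    expect_equal(p, bruteFisher(a, m - a, c, n - c), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(
      matrix(c(a, m - a, c, n - c), 2, byrow = TRUE))$p.value,
      tolerance = 1e-10)
  }
  # deep-sample shapes the caller actually produces
  expect_equal(fisherExactP(100, 99900, 400, 99600),
               stats::fisher.test(matrix(c(100, 99900, 400, 99600), 2,
                                         byrow = TRUE))$p.value,
      tolerance = 1e-10)
})

test_that("the joint fold/Fisher criterion flags true jumps and filters small-clone noise", {
  labels <- cdr3Labels(3, seed = 61)
  other <- setNames(c(5000, 4990), labels[2:3])
  ref <- CloneTable(c(setNames(10, labels[1]), other))  # 10 / 10,000
  cmp <- CloneTable(c(setNames(40, labels[1]), other))  # 40 / 10,030
  calls <- callExpansions(ref, cmp)
  row <- calls[calls$cdr3aa == labels[1], ]
  expect_equal(row$foldChange, (40 / 10030) / (10 / 10000),
               tolerance = 1e-12)
  expect_equal(row$pValue,
               fisherExactP(10, 9990, 40, 9990), tolerance = 1e-12)
  expect_true(row$expanded)

  # 1 -> 3 in 100,000: 3-fold but indistinguishable from sampling noise
  big <- setNames(rep(1000, 100), cdr3Labels(100, seed = 62))
  small <- cdr3Labels(1, seed = 63)
  refS <- CloneTable(c(setNames(1, small), big))
  cmpS <- CloneTable(c(setNames(3, small), big))
  callsS <- callExpansions(refS, cmpS)
  rowS <- callsS[callsS$cdr3aa == small, ]
  expect_gt(rowS$foldChange, 2)
  expect_gt(rowS$pValue, 0.05)
  expect_false(rowS$expanded)

  # unchanged clone: fold 1, never expanded
  same <- callExpansions(ref, ref)
  expect_true(all(same$foldChange == 1))
  expect_false(any(same$expanded))
})

test_that("absence handling: infinite fold needs the Fisher criterion; vanishing clones never expand", {
  labels <- cdr3Labels(4, seed = 64)
  ref <- CloneTable(setNames(c(5000, 5000), labels[1:2]))
  cmp <- CloneTable(setNames(c(4600, 5000, 390, 10), labels[1:4]))
  calls <- callExpansions(ref, cmp)
  newBig <- calls[calls$cdr3aa == labels[3], ]   # 0 -> 390: real appearance
  newTiny <- calls[calls$cdr3aa == labels[4], ]  # 0 -> 10 in 10,000
  expect_identical(newBig$foldChange, Inf)
  expect_true(is.na(newBig$log2FC))
  expect_true(newBig$expanded)
  expect_identical(newTiny$foldChange, Inf)
  expect_equal(newTiny$pValue,
               fisherExactP(0, 10000, 10, 9990), tolerance = 1e-12)

  gone <- callExpansions(cmp, ref)
  expect_identical(gone$foldChange[gone$cdr3aa == labels[3]], 0)
  expect_false(gone$expanded[gone$cdr3aa == labels[3]])
})

test_that("swapping ref and cmp inverts fold-changes and preserves p-values", {
  a <- randomTable(40, seed = 71, maxCount = 400)
  b <- randomTable(35, seed = 72, maxCount = 400)
  fwd <- callExpansions(a, b)
  rev <- callExpansions(b, a)
  rev <- rev[match(fwd$cdr3aa, rev$cdr3aa), ]
  both <- fwd$countRef > 0 & fwd$countCmp > 0
  expect_equal(rev$foldChange[both], 1 / fwd$foldChange[both],
               tolerance = 1e-12)
  expect_equal(rev$pValue, fwd$pValue, tolerance = 1e-12)
})

test_that("identical inputs give identical call tables", {
  a <- randomTable(60, seed = 73, maxCount = 300)
  b <- randomTable(55, seed = 74, maxCount = 300)
  expect_identical(callExpansions(a, b), callExpansions(a, b))
})

test_that("BH gating is available and more conservative", {
  sim <- simulateSeries(simulationConfig(nClones = 1000L,
                                         depth = c(Pre = 30000L, PC = 30000L),
                                         expansionSpec = data.frame(
                                           timepoint = "PC", nExpanded = 5L,
                                           fold = 6, minBaseFreq = 1e-3,
                                           maxBaseFreq = 1e-2),
                                         seed = 29))
  ser <- sim$series$blood
  raw <- callExpansions(ser[["Pre"]], ser[["PC"]])
  bh <- callExpansions(ser[["Pre"]], ser[["PC"]], bh = TRUE)
  expect_true(all(bh$pAdjusted >= bh$pValue - 1e-15))
  expect_lte(sum(bh$expanded), sum(raw$expanded))
})

test_that("volcano data splits finite and non-finite fold-changes and caps p", {
  calls <- data.frame(cdr3aa = c("CAF", "CBF", "CCF"),
                      foldChange = c(4, 1, Inf),
                      log2FC = c(2, 0, NA), pValue = c(0.01, 1, 1e-80),
                      expanded = c(TRUE, FALSE, TRUE))
  v <- volcanoData(calls, cap = 50)
  expect_equal(v$log2FC, c(2, 0))
  expect_equal(v$negLog10P, c(2, 0))
  expect_equal(v$expanded, c(TRUE, FALSE))
  side <- attr(v, "nonfinite")
  expect_equal(side$cdr3aa, "CCF")
  expect_identical(side$foldChange, Inf)

  vLow <- volcanoData(callExpansions(randomTable(20, 81, maxCount = 200),
                                     randomTable(20, 82, maxCount = 200)))
  expect_true(all(is.finite(vLow$negLog10P)))
})

test_that("flagged volcano points are predominantly the injected expansions", {
  cfg <- simulationConfig(nClones = 5000L,
                          depth = c(Pre = 1e5, PC = 1e5),
                          expansionSpec = data.frame(
                            timepoint = "PC", nExpanded = 20L, fold = 4,
                            minBaseFreq = 1e-3, maxBaseFreq = 1e-2),
                          seed = 11)
  sim <- simulateSeries(cfg)
  calls <- callExpansions(sim$series$blood[["Pre"]], sim$series$blood[["PC"]])
  flagged <- calls$cdr3aa[calls$expanded]
  injected <- sim$truth$expanded$PC
  expect_gte(length(intersect(flagged, injected)) / length(flagged), 0.5)
  expect_gte(length(intersect(flagged, injected)) / length(injected), 0.9)
})

test_that("tracking follows the anchor comparison's expanded set across the series", {
  # no expansion anywhere: empty member set, zero aggregate
  tabs <- lapply(c(Pre = 1, PI = 1, PC = 1, PS = 1), function(i)
    randomTable(30, seed = 91, maxCount = 100, patientId = "P1"))
  ser <- SampleSeries(tabs, patientId = "P1")
  ts <- trackExpanded(ser, "Pre", "PC")
  expect_length(members(ts), 0)
  expect_equal(unname(aggregateFrequency(ts)), rep(0, 4))

  # single constructed expansion: aggregate at PC equals that clone's frequency
  labels <- cdr3Labels(2, seed = 92)
  pre <- CloneTable(setNames(c(50, 4950), labels), patientId = "P2")
  pc <- CloneTable(setNames(c(500, 4500), labels), patientId = "P2")
  ser2 <- SampleSeries(list(Pre = pre, PC = pc), patientId = "P2")
  ts2 <- trackExpanded(ser2, "Pre", "PC")
  expect_identical(members(ts2), labels[1])
  expect_equal(aggregateFrequency(ts2)[["PC"]], 0.1, tolerance = 1e-12)
  expect_equal(aggregateFrequency(ts2)[["Pre"]], 0.01, tolerance = 1e-12)

  expect_error(trackExpanded(ser2, "Pre", "PS"), "PS")
})
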