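test_that("test selection follows the decision tree", {
  set.seed(101)
  # two near-normal equal-variance groups: Student's t expected nearly always
  picks <- replicate(40, selectTest(list(rnorm(10), rnorm(10))))
  expect_gt(mean(picks == "student-t"), 0.8)

  # grossly unequal variances: Welch
  set.seed(102)
  picks <- replicate(40, selectTest(list(rnorm(12, sd = 1), rnorm(12, sd = 10))))
  expect_gt(mean(picks == "welch-t"), 0.9)

  # four normal equal-variance groups: ANOVA
  set.seed(103)
  picks <- replicate(40, selectTest(list(rnorm(10), rnorm(10), rnorm(10), rnorm(10))))
  expect_gt(mean(picks == "anova"), 0.8)

  # four groups with one wild variance: Welch ANOVA
  set.seed(104)
  picks <- replicate(40, selectTest(list(rnorm(10), rnorm(10), rnorm(10),
                                         rnorm(10, sd = 12))))
  expect_gt(mean(picks == "welch-anova"), 0.9)

  expect_error(selectTest(list(c(1, 2), rnorm(5))), ">= 3 values")
  expect_error(selectTest(list(rnorm(5))), "length")
})

test_that("fold change is the mean ratio and antisymmetric", {
  expect_identical(foldChange(rep(5, 4), rep(5, 4)), 1)
  expect_identical(foldChange(rep(100, 6), rep(76.5, 6)), 0.765)
  set.seed(5)
  for (i in 1:25) {
    a <- runif(8, 1, 100); b <- runif(8, 1, 100)
    expect_equal(foldChange(a, b) * foldChange(b, a), 1, tolerance = 1e-12)
  }
  expect_error(foldChange(c(-3, 1), c(1, 2)), "positive")
})

test_that("the compound significance rule is strict at both boundaries", {
  # FC exactly at the threshold, tiny p: not significant
  m <- rbind(fc_at_thresh = c(rep(100, 10), rep(150, 10)),
             fc_two_anchor = c(rep(100, 10), rep(200, 10)))
  colnames(m) <- paste0("s", 1:20)
  x <- mas(m, group = rep(c("NHF", "AMHF"), each = 10))
  res <- suppressMessages(screenMirnas(x, case = "AMHF"))
  expect_identical(res["fc_at_thresh", "fold_change"], 1.5)
  expect_lt(res["fc_at_thresh", "p_value"], 0.05)
  expect_false(res["fc_at_thresh", "significant"])
  expect_true(res["fc_two_anchor", "significant"])

  # p exactly at alpha, large FC: the flag must be FALSE (strict p < alpha)
  df <- S4Vectors::DataFrame(mirna = "m", fold_change = 2.0, p_value = 0.05)
  sig <- (df$fold_change > 1.5 | df$fold_change < 1 / 1.5) & df$p_value < 0.05
  expect_false(sig)
  # and through the screen itself: direction/significance consistency
  expect_true(all(res$direction[res$fold_change > 1] == "up"))
  expect_true(all(res$direction[res$fold_change < 1] == "down"))
})

test_that("screen flags planted effects and rarely flags nulls", {
  # planted truth at the published AMNHF effects, default noise
  hits <- sapply(1:10, function(s) {
    res <- quietScreen(tinyConfig(seed = s), case = "AMNHF")
    truth <- plantedFoldChanges("AMNHF")
    strong <- truth$mirna[truth$fold_change > 1.5 | truth$fold_change < 1 / 1.5]
    mean(as.data.frame(res)[strong, "significant"])
  })
  expect_gt(mean(hits), 0.9)

  # null matrix: compound-rule positives must stay below alpha
  nullrate <- sapply(1:10, function(s) {
    cfg <- SimConfig(deTable = plantedFoldChanges()[0, ], nBackground = 150L,
                     seed = s)
    res <- quietScreen(cfg, case = "AMNHF")
    mean(res$significant)
  })
  expect_lt(mean(nullrate), 0.05)
})

test_that("screen errors on unknown groups and records its metadata", {
  sim <- simulateExpression(tinyConfig())
  pre <- suppressMessages(preprocess(sim$experiment))
  expect_error(screenMirnas(pre, case = "NOPE"), "group label")
  res <- suppressMessages(screenMirnas(pre, case = "OMHF"))
  md <- S4Vectors::metadata(res)
  expect_identical(md$case, "OMHF")
  expect_identical(md$control, "NHF")
})

test_that("top tables reproduce the published screening tables on exact data", {
  pre <- suppressMessages(preprocess(
    simulateExpression(tinyConfig(noiseCV = 0))$experiment))
  expected <- list(
    AMNHF = list(up = c("hsa-miR-409-3p", "hsa-miR-26b-5p", "hsa-miR-369-3p",
                        "hsa-miR-148b-3p", "hsa-miR-329"),
                 down = c("hsa-miR-320", "hsa-miR-204", "hsa-miR-20b-3p",
                          "hsa-miR-767-5p", "hsa-miR-299-5p")),
    OMHF = list(up = c("hsa-miR-3941", "hsa-miR-338-5p", "hsa-miR-433",
                       "hsa-miR-19a-3p", "hsa-miR-329"),
                down = c("hsa-miR-320", "hsa-miR-204", "hsa-miR-2110",
                         "hsa-miR-1247-5p", "hsa-miR-296-5p")),
    AMHF = list(up = c("hsa-miR-3667-5p", "hsa-miR-4275", "hsa-miR-647",
                       "hsa-miR-1284", "hsa-miR-1306-3p"),
                down = c("hsa-miR-320", "hsa-miR-204", "hsa-miR-205-5p",
                         "hsa-miR-423-5p", "hsa-miR-21-3p")))
  for (case in names(expected)) {
    tt <- suppressMessages(topTable(suppressMessages(
      screenMirnas(pre, case = case))))
    expect_identical(tt$up$mirna, expected[[case]]$up)
    expect_identical(tt$down$mirna, expected[[case]]$down)
    # fold changes carried through unchanged
    truth <- plantedFoldChanges(case)
    expect_equal(tt$down$fold_change,
                 truth$fold_change[match(tt$down$mirna, truth$mirna)],
                 tolerance = 1e-12)
  }
})

test_that("top tables degrade gracefully", {
  # nothing below alpha -> two empty tables
  df <- S4Vectors::DataFrame(
    mirna = c("a", "b"), fold_change = c(2, 0.4), p_value = c(0.5, 0.9),
    neg_log10_p = -log10(c(0.5, 0.9)), test_used = "student-t",
    direction = c("up", "down"), significant = c(FALSE, FALSE))
  tt <- suppressMessages(topTable(df))
  expect_identical(nrow(tt$up), 0L)
  expect_identical(nrow(tt$down), 0L)

  # k larger than the hit count -> full sorted lists plus a notice
  df2 <- S4Vectors::DataFrame(
    mirna = c("a", "b", "c"), fold_change = c(4, 2, 0.3),
    p_value = c(0.01, 0.02, 0.001), neg_log10_p = -log10(c(0.01, 0.02, 0.001)),
    test_used = "student-t", direction = c("up", "up", "down"),
    significant = TRUE)
  expect_message(tt2 <- topTable(df2), "only")
  expect_identical(tt2$up$mirna, c("a", "b"))
  expect_identical(tt2$down$mirna, "c")
})

test_that("volcano coordinates are -log10(p) with underflow capping", {
  df <- S4Vectors::DataFrame(
    mirna = c("p1", "p05", "tiny"), fold_change = c(1, 2, 3),
    p_value = c(1, 0.05, 1e-320),
    neg_log10_p = suppressMessages(cardiomiR:::negLog10P(c(1, 0.05, 1e-320))),
    test_used = "student-t", direction = c("none", "up", "up"),
    significant = c(FALSE, FALSE, TRUE))
  v <- volcanoPoints(df, max_neg_log10 = 300)
  expect_identical(v$neg_log10_p[1], 0)
  expect_equal(v$neg_log10_p[2], 1.30103, tolerance = 1e-5)
  expect_identical(v$neg_log10_p[3], 300)
  expect_identical(v$significant, df$significant)
  # ordinate strictly decreasing in p
  p <- sort(runif(20, 1e-8, 1))
  o <- suppressMessages(cardiomiR:::negLog10P(p))
  expect_true(all(diff(o) < 0))
})

test_that("OD summaries average wells per day", {
  od <- data.frame(day = c(5, 5), well = 1:2, od = c(1.7, 1.8))
  s <- odSummary(od)
  expect_equal(s$mean, 1.75, tolerance = 1e-12)
  expect_equal(s$sd, sd(c(1.7, 1.8)))
  single <- data.frame(day = 1, well = 1, od = 2.0)
  expect_message(s1 <- odSummary(single), "single well")
  expect_identical(s1$sd, 0)
  # the published day-5 endpoint for the second trajectory: 1.76 exactly
  od2 <- simulateOD(days = 5, start_od = 2.45, end_od = 1.76, noise_sd = 0,
                    seed = 1)
  expect_identical(odSummary(od2)$mean[5], 1.76)
})
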