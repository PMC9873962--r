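test_that("configuration invariants are enforced", {
  expect_error(SimConfig(groupSizes = c(NHF = 1L, AMHF = 10L)), "group sizes")
  expect_error(SimConfig(deTable = data.frame(
    mirna = "m", control = "NHF", case = "AMHF", fold_change = -1)),
    "fold changes")
  expect_error(SimConfig(noiseCV = -0.1), "noiseCV")
  expect_error(SimConfig(deTable = data.frame(
    mirna = "m", control = "NHF", case = "NOPE", fold_change = 2)),
    "absent")
})

test_that("zero-noise generation reproduces planted fold changes exactly", {
  sim <- simulateExpression(tinyConfig(noiseCV = 0))
  m <- intensities(sim$experiment)
  grp <- groupLabels(sim$experiment)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    fc <- mean(m[tr$mirna, grp == tr$case]) / mean(m[tr$mirna, grp == tr$control])
    expect_equal(fc, tr$fold_change, tolerance = 1e-13)
  }
})

test_that("a fixed seed yields identical matrices; different seeds differ", {
  a <- simulateExpression(tinyConfig(seed = 11L))
  b <- simulateExpression(tinyConfig(seed = 11L))
  c <- simulateExpression(tinyConfig(seed = 12L))
  expect_identical(intensities(a$experiment), intensities(b$experiment))
  expect_identical(a$design, b$design)
  expect_false(identical(intensities(a$experiment), intensities(c$experiment)))
})

test_that("generated matrix has the designed shape and floor-straddling rows", {
  cfg <- tinyConfig(nBackground = 100L, belowFloorFraction = 0.1)
  sim <- simulateExpression(cfg)
  m <- intensities(sim$experiment)
  expect_equal(ncol(m), sum(cfg@groupSizes))
  expect_equal(nrow(m), length(unique(cfg@deTable$mirna)) + cfg@nBackground)
  lowRows <- grep("^hsa-miR-low-", rownames(m), value = TRUE)
  expect_gt(length(lowRows), 0L)
  expect_true(all(apply(m[lowRows, , drop = FALSE], 1L, min) < cfg@floor))
  expect_true(all(m >= 0))
})

test_that("noise is mean-preserving: cell expectation matches the planted mean", {
  # one miRNA, many samples: the sample mean over 4000 noisy cells must
  # sit within Monte-Carlo error of the planted mean
  cfg <- SimConfig(groupSizes = c(NHF = 2000L, AMHF = 2000L),
                   deTable = data.frame(mirna = "m1", control = "NHF",
                                        case = "AMHF", fold_change = 0.765),
                   nBackground = 2L, noiseCV = 0.15, seed = 42L)
  sim <- simulateExpression(cfg)
  m <- intensities(sim$experiment)
  grp <- groupLabels(sim$experiment)
  expect_equal(mean(m["m1", grp == "NHF"]), 1000, tolerance = 0.01)
  expect_equal(mean(m["m1", grp == "AMHF"]), 765, tolerance = 0.01)
})

test_that("echo generator respects anatomy, group contractility and demographics", {
  nhf <- simulateEcho("NHF", n = 40, seed = 5)
  amhf <- simulateEcho("AMHF", n = 40, seed = 6)
  expect_equal(nrow(nhf), 40L)
  for (rec in list(nhf, amhf)) {
    expect_true(all(rec$LVESV < rec$LVEDV))
    expect_true(all(rec$LVIDs < rec$LVIDd))
    expect_true(all(as.matrix(rec[, -(1:2)]) > 0))
  }
  # case groups are generated with depressed contractility
  expect_lt(mean(lvef(amhf$LVEDV, amhf$LVESV)), mean(lvef(nhf$LVEDV, nhf$LVESV)))
  # published group-mean heights are 1.62-1.65 m
  expect_gt(mean(nhf$height), 155)
  expect_lt(mean(nhf$height), 170)
  expect_identical(simulateEcho("NHF", 5, seed = 9),
                   simulateEcho("NHF", 5, seed = 9))
  expect_error(simulateEcho("XXX", 5), "unknown group")
})

test_that("survival generator honours censoring and hazard structure", {
  none <- simulateSurvival(n = 40, censor_rate = 0, seed = 3)
  expect_true(all(none$event))
  cens <- simulateSurvival(n = 400, censor_rate = 0.3, seed = 3)
  expect_equal(mean(!cens$event), 0.3, tolerance = 0.25)
  # null hazard ratio: log-rank statistic small on average
  stats <- vapply(1:30, function(s) {
    r <- simulateSurvival(n = 30, hazard_ratio = 1, censor_rate = 0, seed = s)
    g <- splitByExpression(r)
    logrankTest(g$high, g$low)$statistic
  }, numeric(1))
  expect_lt(mean(stats), 2.5)  # E[chi2_1] = 1
  # planted hazard ratio: high group detectably worse in most replicates
  ps <- vapply(1:50, function(s) {
    r <- simulateSurvival(n = 30, hazard_ratio = 3, censor_rate = 0, seed = s)
    g <- splitByExpression(r)
    logrankTest(g$high, g$low)$p_value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.5)
})

test_that("OD generator hits its endpoints and is linear without noise", {
  od <- simulateOD(days = 5, start_od = 2.4, end_od = 1.75, n_wells = 4,
                   noise_sd = 0, seed = 1)
  s <- odSummary(od)
  expect_identical(s$mean[s$day == 5], 1.75)
  expect_identical(s$mean[s$day == 1], 2.4)
  # per-day means on the straight line
  expect_equal(s$mean, seq(2.4, 1.75, length.out = 5), tolerance = 1e-12)
  expect_true(all(diff(s$mean) < 0))
  expect_identical(simulateOD(5, 2.4, 1.75, noise_sd = 0.05, seed = 2),
                   simulateOD(5, 2.4, 1.75, noise_sd = 0.05, seed = 2))
})

test_that("technical-replicate stacks share labels and average to the surface", {
  stack <- simulateReplicateStack(tinyConfig(noiseCV = 0.1, nBackground = 10L),
                                  nReplicates = 10L)
  expect_length(stack, 10L)
  expect_true(all(vapply(stack, function(m)
    identical(dimnames(m), dimnames(stack[[1]])), logical(1))))
})
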