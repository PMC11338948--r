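test_that("rank-form AUC matches hand counts and handles degenerate input", {
  expect_equal(aucOneVsRest(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(aucOneVsRest(c(0, 0, 1, 1), c(0.1, 0.2, 0.6, 0.9)), 1)
  expect_equal(aucOneVsRest(c(1, 0), c(0.5, 0.5)), 0.5)  # full tie
  expect_error(aucOneVsRest(c(1, 1, 1), c(0.1, 0.2, 0.3)), "undefined")
  expect_error(aucOneVsRest(c(0, 0), c(0.1, 0.2)), "undefined")
})

test_that("AUC agrees with the all-pairs oracle and is monotone-invariant", {
  set.seed(21)
  for (k in 1:300) {
    n <- sample(4:50, 1)
    y <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(y) || all(y)) next
    s <- round(runif(n), sample(1:3, 1))   # coarse rounding forces ties
    a <- aucOneVsRest(y, s)
    expect_equal(a, oracleAucAllPairs(y, s))
    expect_equal(aucOneVsRest(y, qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)) * 3 + 1), a)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (k in 1:25) {
    n <- sample(20:80, 1)
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    s <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          quiet = TRUE, direction = "<")))
    expect_equal(aucOneVsRest(y, s), ref)
  }
})

test_that("bootstrap CI is seeded-deterministic and degenerate-safe", {
  set.seed(31)
  df <- data.frame(y = rep(c(TRUE, FALSE), each = 40),
                   s = c(runif(40, 0.4, 1), runif(40, 0, 0.6)))
  a <- bootstrapCi(df, function(d) aucOneVsRest(d$y, d$s), nBoot = 200, seed = 9)
  b <- bootstrapCi(df, function(d) aucOneVsRest(d$y, d$s), nBoot = 200, seed = 9)
  expect_identical(a, b)
  expect_lte(a[["lo"]], a[["hi"]])

  # constant statistic: interval collapses onto the point
  cst <- bootstrapCi(df, function(d) 0.5, nBoot = 50, seed = 1)
  expect_equal(unname(cst), c(0.5, 0.5, 0.5))

  # statistic undefined on the full data propagates
  bad <- data.frame(y = rep(TRUE, 10), s = runif(10))
  expect_error(bootstrapCi(bad, function(d) aucOneVsRest(d$y, d$s), nBoot = 10),
               "undefined")
})

test_that("group-average AUC reproduces reported style means", {
  expect_equal(round(groupAverageAuc(c(0.994, 0.968, 0.998)), 3), 0.987)
  expect_equal(round(groupAverageAuc(c(0.990, 0.955, 0.976, 0.991)), 3), 0.978)
  expect_equal(groupAverageAuc(c(0.9, NA)), 0.9)   # undefined labels dropped
  expect_error(groupAverageAuc(c(NA_real_, NA_real_)), "undefined")
})

test_that("landmark MAE follows the population-SD convention and pairing rules", {
  meta <- ImageMeta(512, 512, 1)
  p <- rbind(c(10, 10), c(20, 20))
  t1 <- rbind(c(10, 13), c(25, 20))      # distances 3 and 5 mm
  r <- landmarkMaeMm(p, t1, meta)
  expect_equal(r$mean, 4)
  expect_equal(r$sd, 1)                  # population SD of (3, 5)
  expect_equal(landmarkMaeMm(p, t1, meta, sdType = "sample")$sd, sqrt(2))

  same <- landmarkMaeMm(p, p, meta)
  expect_equal(c(same$mean, same$sd), c(0, 0))

  # rows with missing annotations are excluded and counted
  p2 <- rbind(p, c(NA, NA))
  t2 <- rbind(t1, c(1, 1))
  r2 <- landmarkMaeMm(p2, t2, meta)
  expect_equal(r2$n, 2)
  expect_equal(r2$nExcluded, 1)
  expect_error(landmarkMaeMm(matrix(NA_real_, 1, 2), matrix(1, 1, 2), meta),
               "no complete")
})

test_that("Gaussian landmark noise yields the Rayleigh mean MAE", {
  set.seed(77)
  sdMm <- 3
  n <- 2000
  truth <- cbind(runif(n, 50, 450), runif(n, 50, 450))
  noisy <- truth + matrix(rnorm(2 * n, 0, sdMm), n, 2)
  r <- landmarkMaeMm(noisy, truth, ImageMeta(512, 512, 1))
  expect_lt(abs(r$mean - sdMm * sqrt(pi / 2)) / (sdMm * sqrt(pi / 2)), 0.05)
})

test_that("paired distance test recovers a known shift and is antisymmetric", {
  set.seed(55)
  a <- runif(300, 2, 20)
  b <- a - 2 + rnorm(300, 0, 0.5)
  r <- pairedDifferenceTest(a, b)
  expect_lt(abs(r$meanDiff + 2), 0.15)
  expect_lt(r$p, 0.01)
  expect_true(r$lo < -2 && r$hi > -2.2)  # CI brackets the true shift

  flip <- pairedDifferenceTest(b, a)
  expect_equal(flip$meanDiff, -r$meanDiff)
  expect_equal(flip$p, r$p)

  same <- pairedDifferenceTest(a, a)
  expect_equal(same$meanDiff, 0)
  expect_equal(same$p, 1)
  expect_error(pairedDifferenceTest(1, numeric(0)), "pair")
  expect_error(pairedDifferenceTest(1, 2), "two")
})

test_that("significance needs both p < 0.05 and disjoint intervals", {
  expect_true(significanceFlag(0.01, c(0.70, 0.75), c(0.80, 0.88)))
  expect_false(significanceFlag(0.01, c(0.70, 0.82), c(0.80, 0.88)))  # overlap
  expect_false(significanceFlag(0.2, c(0.70, 0.75), c(0.80, 0.88)))   # p too big
})

test_that("cohort evaluation reports per-label and group AUCs with CIs", {
  set.seed(88)
  cfg <- SimConfig(nImages = 150L, seed = 42L)
  sim <- simulateCohort(cfg)
  rep <- evaluateCohort(sim$truth, sim$scores, nBoot = 120, seed = 5)
  pl <- rep$perLabel
  ok <- pl[pl$status == "ok", ]
  expect_gt(nrow(ok), 5)
  expect_true(all(ok$lo <= ok$auc + 1e-9 & ok$auc <= ok$hi + 1e-9))
  expect_true(all(ok$auc >= 0 & ok$auc <= 1))
  # high-discrimination generator: defined labels should separate well
  expect_gt(mean(ok$auc), 0.8)
  pg <- rep$perGroup
  expect_equal(pg$group, c("ETT", "NGT", "CVC"))
  for (i in which(pg$status == "ok")) {
    labs <- TUBE_LABEL_GROUPS[[pg$group[i]]]
    defined <- pl$auc[match(labs, pl$label)]
    expect_equal(pg$auc[i], mean(defined[!is.na(defined)]))
  }
  # undefined cells stay visible, not dropped
  expect_true(all(c("ok", "undefined") %in% c(pl$status, "ok")))
})

test_that("stratified evaluation with a null flag gives concordant strata", {
  set.seed(99)
  cfg <- SimConfig(nImages = 260L, seed = 7L)
  sim <- simulateCohort(cfg)
  flag <- runif(nrow(sim$truth)) < 0.5    # independent of everything
  reps <- stratifiedReport(sim$truth, sim$scores, flag, nBoot = 100, seed = 3)
  expect_named(reps, c("TRUE", "FALSE"))
  g1 <- reps[["TRUE"]]$perGroup; g2 <- reps[["FALSE"]]$perGroup
  for (i in seq_len(nrow(g1))) {
    if (g1$status[i] != "ok" || g2$status[i] != "ok") next
    # each stratum's point estimate inside the other's CI (null effect)
    expect_true(g1$auc[i] >= g2$lo[i] - 0.03 && g1$auc[i] <= g2$hi[i] + 0.03)
  }
  # degenerate stratum is reported, not silently dropped
  expect_warning(stratifiedReport(sim$truth, sim$scores,
                                  rep(TRUE, nrow(sim$truth)), nBoot = 20, seed = 1),
                 "empty")
  expect_error(stratifiedReport(sim$truth, sim$scores,
                                c(NA, rep(TRUE, nrow(sim$truth) - 1L))),
               "every image")
})
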