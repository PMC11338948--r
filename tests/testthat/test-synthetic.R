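cfgS <- SimConfig(seed = 5L)

test_that("generation is seed-deterministic with counter substreams", {
  a <- simulateImage(cfgS, 3)
  b <- simulateImage(cfgS, 3)
  expect_identical(a$landmarks@points, b$landmarks@points)
  expect_identical(a$masks@channels, b$masks@channels)
  expect_identical(scoreVector(a$scores), scoreVector(b$scores))
  # image 3 does not depend on how many images the cohort has
  cSmall <- simulateCohort(SimConfig(nImages = 3L, seed = 5L))
  cBig <- simulateCohort(SimConfig(nImages = 6L, seed = 5L))
  expect_identical(cSmall$truth, cBig$truth[1:3, ])
  expect_identical(cSmall$scores, cBig$scores[1:3, ])
})

test_that("sampled anatomy is in-bounds with the carina cranial to the CAJ", {
  set.seed(1)
  for (k in 1:500) {
    lm <- sampleAnatomy(cfgS)
    for (nm in names(lm@points)) {
      p <- lm@points[[nm]]
      expect_true(p[1] >= 0 && p[1] < cfgS@width && p[2] >= 0 && p[2] < cfgS@height)
    }
    expect_lt(landmark(lm, "carina")[2], landmark(lm, "cavoatrial_junction")[2])
  }
  expect_error(SimConfig(width = 64L, height = 64L), "too small")
})

test_that("sampled tube tips realize their requested category analytically", {
  set.seed(2)
  for (k in 1:300) {
    lm <- sampleAnatomy(cfgS)
    for (cat in c("Normal", "Borderline", "Abnormal")) {
      tb <- sampleTube("ETT", cat, lm, cfgS)
      expect_equal(classifyEtt(tb$dMm)$category, cat)
      if (cat == "Abnormal") expect_lte(tb$dMm, 0)
      tb2 <- sampleTube("CVC", cat, lm, cfgS)
      expect_equal(classifyCvc(tb2$dMm)$category, cat)
    }
  }
  lm <- sampleAnatomy(cfgS)
  expect_error(sampleTube("ETT", "IncompletelyImaged", lm, cfgS), "impossible")
  expect_error(sampleTube("ETT", "Normal", LandmarkSet(geJunction = c(10, 400)),
                          cfgS), "carina")
})

test_that("incompletely imaged NGTs exit the film with under 10 cm visible", {
  set.seed(3)
  meta <- ImageMeta(cfgS@width, cfgS@height, cfgS@spacingMm)
  for (k in 1:25) {
    lm <- sampleAnatomy(cfgS)
    tb <- sampleTube("NGT", "IncompletelyImaged", lm, cfgS)
    mk <- rasterizePolyline(tb$polyline, cfgS@width, cfgS@height, 3)
    expect_true(findComponents(mk)$touchesBorder[1])
    expect_lt(visibleLineLengthMm(mk, meta), 100)
  }
})

test_that("rasterized tip discs recover the tip coordinate", {
  set.seed(4)
  for (k in 1:50) {
    tip <- c(runif(1, 10, 500), runif(1, 10, 500))
    disc <- rasterizeDisc(tip, 512, 512, 3)
    cc <- findComponents(disc)
    expect_equal(nrow(cc), 1L)
    expect_lt(max(abs(c(cc$centroidX, cc$centroidY) - tip)), 0.51)
    det <- selectTip(cc, "ETT")
    expect_lt(sqrt(sum((det$tip - tip)^2)), 1)
  }
})

test_that("rasterized polylines measure close to their analytic arc length", {
  set.seed(6)
  meta <- ImageMeta(cfgS@width, cfgS@height, cfgS@spacingMm)
  for (k in 1:20) {
    lm <- sampleAnatomy(cfgS)
    tb <- sampleTube("NGT", sample(c("Normal", "Borderline"), 1), lm, cfgS)
    mk <- rasterizePolyline(tb$polyline, cfgS@width, cfgS@height, 3)
    analytic <- sum(sqrt(rowSums(diff(tb$polyline)^2))) * cfgS@spacingMm
    got <- visibleLineLengthMm(mk, meta)
    expect_lt(abs(got - analytic) / analytic, 0.08)
  }
})

test_that("binormal scores hit the target discrimination", {
  # mu formula: sqrt(2) * qnorm(A)
  expect_equal(sqrt(2) * qnorm(0.5), 0)
  expect_equal(sqrt(2) * qnorm(0.9), 1.8124, tolerance = 1e-4)
  set.seed(8)
  n <- 5000
  y <- runif(n) < 0.3
  mu <- sqrt(2) * qnorm(0.9)
  s <- plogis(rnorm(n, ifelse(y, mu, 0), 1))
  expect_lt(abs(aucOneVsRest(y, s) - 0.9), 0.02)
  # and through the generator itself
  cfg <- SimConfig(nImages = 400L, targetAuc = 0.85, seed = 21L)
  sim <- simulateCohort(cfg)
  keep <- !is.na(sim$truth$ETT)
  a <- aucOneVsRest(sim$truth$ETT[keep] == "Normal", sim$scores[keep, "ETT_Normal"])
  expect_lt(abs(a - 0.85), 0.07)
})

test_that("landmark corruption is unbiased noise that vanishes at sd 0", {
  meta <- ImageMeta(512, 512, 0.7)
  lm <- LandmarkSet(carina = c(250, 150), cavoatrialJunction = c(300, 220),
                    geJunction = c(230, 360))
  expect_identical(corruptLandmarks(lm, 0, meta)@points, lm@points)
  set.seed(9)
  a <- corruptLandmarks(lm, 3, meta)
  set.seed(9)
  b <- corruptLandmarks(lm, 3, meta)
  expect_identical(a@points, b@points)
  # MAE of repeated corruption matches the Rayleigh mean within 5%
  set.seed(10)
  n <- 2000
  pred <- t(vapply(seq_len(n), function(i)
    landmark(corruptLandmarks(lm, 3, meta), "carina"), numeric(2)))
  truthM <- matrix(rep(c(250, 150), each = n), n, 2)
  r <- landmarkMaeMm(pred, truthM, meta)
  expect_lt(abs(r$mean - 3 * sqrt(pi / 2)) / (3 * sqrt(pi / 2)), 0.05)
})

test_that("cohort composition tracks the configured mixtures", {
  sim <- simulateCohort(SimConfig(nImages = 303L, seed = 13L))
  tr <- sim$truth
  expect_equal(nrow(tr), 303L)
  # presence rates within binomial tolerance of the configured 178/148/39
  expect_lt(abs(sum(!is.na(tr$ETT)) - 178), 35)
  expect_lt(abs(sum(!is.na(tr$CVC)) - 148), 35)
  expect_lt(abs(sum(!is.na(tr$NGT)) - 39), 25)
  expect_true(all(tr$CVC[tr$swanGanz & !is.na(tr$CVC)] == "Normal"))
  expect_lt(abs(mean(tr$ecgLeads) - 151 / 303), 0.15)
})
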