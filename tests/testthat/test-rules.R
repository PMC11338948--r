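cfg <- RuleConfig()

test_that("ETT categories follow the carina-distance bands", {
  expect_equal(classifyEtt(20, cfg = cfg)$category, "Borderline")   # < 3.5 cm
  expect_equal(classifyEtt(80, cfg = cfg)$category, "Borderline")   # > 7 cm
  expect_equal(classifyEtt(0, cfg = cfg)$category, "Abnormal")      # at carina
  expect_equal(classifyEtt(-12, cfg = cfg)$category, "Abnormal")
  expect_equal(classifyEtt(50, cfg = cfg)$category, "Normal")
  expect_equal(classifyEtt(35, cfg = cfg)$category, "Normal")       # inclusive edge
  expect_equal(classifyEtt(70, cfg = cfg)$category, "Normal")
  expect_equal(classifyEtt(50, t1Above = TRUE, cfg = cfg)$category, "Abnormal")
  expect_equal(classifyEtt(NA, cfg = cfg)$category, "Indeterminate")

  strict <- RuleConfig(boundaryInclusiveNormal = FALSE)
  expect_equal(classifyEtt(35, cfg = strict)$category, "Borderline")
  expect_equal(classifyEtt(70, cfg = strict)$category, "Borderline")
})

test_that("NGT categories follow advancement, position and completeness", {
  expect_equal(classifyNgt(120, cfg = cfg)$category, "Normal")
  expect_equal(classifyNgt(40, cfg = cfg)$category, "Borderline")
  expect_equal(classifyNgt(NA, aboveGej = TRUE, cfg = cfg)$category, "Abnormal")
  expect_equal(
    classifyNgt(NA, incomplete = TRUE, visibleLenMm = 80, cfg = cfg)$category,
    "IncompletelyImaged")
  # incomplete but plenty of tube visible is not the incomplete category
  expect_equal(classifyNgt(120, incomplete = TRUE, visibleLenMm = 300,
                           cfg = cfg)$category, "Normal")
  expect_equal(classifyNgt(NA, cfg = cfg)$category, "Indeterminate")
})

test_that("CVC categories follow the cavoatrial bands and conventions", {
  expect_equal(classifyCvc(15, cfg = cfg)$category, "Normal")
  expect_equal(classifyCvc(-10, cfg = cfg)$category, "Borderline")
  expect_equal(classifyCvc(-40, cfg = cfg)$category, "Abnormal")
  expect_equal(classifyCvc(-40, swanGanz = TRUE, cfg = cfg)$category, "Normal")
  expect_equal(classifyCvc(NA, swanGanz = TRUE, cfg = cfg)$category, "Normal")
  expect_equal(classifyCvc(NA, cfg = cfg)$category, "Indeterminate")
  expect_equal(classifyCvc(15, belowArch = FALSE, cfg = cfg)$category, "Borderline")
  expect_equal(classifyCvc(15, belowArch = NA, cfg = cfg)$category, "Normal")
})

test_that("rule engine matches an independently coded truth table on a dense grid", {
  grid <- c(seq(-200, 200, by = 0.5),
            0, 35, 70, -25, 100,                       # exact boundaries
            .Machine$double.eps, 35 - 1e-9, 70 + 1e-9, -25 - 1e-9)
  for (d in grid) {
    expect_equal(classifyEtt(d, cfg = cfg)$category, oracleEttCategory(d),
                 info = paste("ETT d =", d))
    expect_equal(classifyCvc(d, cfg = cfg)$category, oracleCvcCategory(d),
                 info = paste("CVC d =", d))
    if (d >= 0)
      expect_equal(classifyNgt(d, cfg = cfg)$category, oracleNgtCategory(d),
                   info = paste("NGT d =", d))
  }
  # flag combinations
  for (t1 in c(TRUE, FALSE, NA)) for (d in c(-5, 10, 50, 80))
    expect_equal(classifyEtt(d, t1Above = t1, cfg = cfg)$category,
                 oracleEttCategory(d, t1Above = t1))
  for (sg in c(TRUE, FALSE)) for (ba in c(TRUE, FALSE, NA))
    for (d in c(-40, -10, 5, NA))
      expect_equal(classifyCvc(d, swanGanz = sg, belowArch = ba, cfg = cfg)$category,
                   oracleCvcCategory(d, swanGanz = sg, belowArch = ba))
  for (inc in c(TRUE, FALSE)) for (ag in c(TRUE, FALSE))
    for (vl in c(50, 150)) for (d in c(NA, 20, 150))
      expect_equal(
        classifyNgt(d, aboveGej = ag, incomplete = inc, visibleLenMm = vl,
                    cfg = cfg)$category,
        oracleNgtCategory(d, aboveGej = ag, incomplete = inc, visibleLen = vl))
})

test_that("score correction swaps the implicated pair and upgrades only", {
  s <- scoresWith(ETT_Normal = 0.8, ETT_Borderline = 0.15, ETT_Abnormal = 0.05)
  out <- applyRules(s, list(ETT = classifyEtt(20, cfg = cfg)), cfg)
  adj <- scoreVector(out$adjustedScores)
  expect_equal(unname(adj["ETT_Normal"]), 0.15)
  expect_equal(unname(adj["ETT_Borderline"]), 0.8)
  expect_equal(unname(adj["ETT_Abnormal"]), 0.05)
  expect_equal(out$decisions$ETT@finalLabel, "ETT_Borderline")
  expect_equal(out$decisions$ETT@firedRules, "ETT_LOW")

  # worst-category upgrade: argmax Normal, geometry Abnormal
  s2 <- scoresWith(ETT_Normal = 0.5, ETT_Borderline = 0.3, ETT_Abnormal = 0.2)
  out2 <- applyRules(s2, list(ETT = classifyEtt(-5, cfg = cfg)), cfg)
  adj2 <- scoreVector(out2$adjustedScores)
  expect_equal(unname(adj2[c("ETT_Normal", "ETT_Borderline", "ETT_Abnormal")]),
               c(0.2, 0.3, 0.5))
  expect_equal(out2$decisions$ETT@finalLabel, "ETT_Abnormal")

  # geometry agrees with argmax: no-op
  out3 <- applyRules(s, list(ETT = classifyEtt(50, cfg = cfg)), cfg)
  expect_equal(scoreVector(out3$adjustedScores), scoreVector(s))

  # geometry Indeterminate: no-op
  out4 <- applyRules(s, list(ETT = classifyEtt(NA, cfg = cfg)), cfg)
  expect_equal(scoreVector(out4$adjustedScores), scoreVector(s))

  # downgrades never fire: argmax Abnormal, geometry Normal
  s5 <- scoresWith(ETT_Abnormal = 0.9)
  out5 <- applyRules(s5, list(ETT = classifyEtt(50, cfg = cfg)), cfg)
  expect_equal(scoreVector(out5$adjustedScores), scoreVector(s5))
})

test_that("correction is idempotent, rank-monotone and score-conserving", {
  set.seed(12)
  rank3 <- c(Normal = 1, Borderline = 2, Abnormal = 3)
  for (k in 1:200) {
    s <- stats::setNames(round(runif(length(RANZCR_LABELS)), 3), RANZCR_LABELS)
    d <- runif(1, -120, 120)
    dec <- list(ETT = classifyEtt(d, cfg = cfg),
                CVC = classifyCvc(runif(1, -80, 80), cfg = cfg),
                NGT = classifyNgt(runif(1, 0, 200), cfg = cfg))
    one <- applyRules(ClassScores(s), dec, cfg)
    two <- applyRules(one$adjustedScores, dec, cfg)
    expect_equal(scoreVector(two$adjustedScores), scoreVector(one$adjustedScores))
    for (tube in c("ETT", "CVC", "NGT")) {
      grp <- TUBE_LABEL_GROUPS[[tube]]
      # permutation within the tube group
      expect_equal(sort(scoreVector(one$adjustedScores)[grp]), sort(s[grp]),
                   ignore_attr = TRUE)
      # never moved toward Normal
      beforeCat <- sub("^[A-Z]+_", "", grp[which.max(s[grp])])
      afterCat <- sub("^[A-Z]+_", "", one$decisions[[tube]]@finalLabel)
      if (beforeCat %in% names(rank3) && afterCat %in% names(rank3))
        expect_gte(rank3[[afterCat]], rank3[[beforeCat]])
      # final label is the argmax of its group
      adj <- scoreVector(one$decisions[[tube]]@adjustedScores)
      expect_equal(one$decisions[[tube]]@finalLabel, grp[which.max(adj[grp])])
    }
  }
})

test_that("disabling all rules turns the engine into a pass-through", {
  off <- RuleConfig(enabledRules = character(0))
  s <- scoresWith(ETT_Normal = 0.9, CVC_Normal = 0.8)
  dec <- list(ETT = classifyEtt(10, cfg = off), CVC = classifyCvc(-50, cfg = off))
  expect_equal(dec$ETT$category, "Normal")   # no clause allowed to fire
  out <- applyRules(s, dec, off)
  expect_equal(scoreVector(out$adjustedScores), scoreVector(s))
})

test_that("full pipeline on one crafted radiograph upgrades a low ETT", {
  meta <- ImageMeta(256, 256, 1, imageId = "crafted")
  lm <- LandmarkSet(carina = c(128, 80), cavoatrialJunction = c(160, 130),
                    geJunction = c(120, 190))
  masks <- MaskChannelSet(
    meta,
    ettTip = rasterizeDisc(c(128, 60), 256, 256, 3),      # 20 mm above carina
    cvcTip = rasterizeDisc(c(160, 110), 256, 256, 3),     # 20 mm above CAJ
    cvcLine = rasterizePolyline(cbind(seq(0, 160, 2), seq(40, 110, length.out = 81)),
                                256, 256, 3)
  )
  s <- scoresWith(ETT_Normal = 0.7, ETT_Borderline = 0.2, CVC_Normal = 0.6)
  res <- classifyImage(masks, lm, s, swanGanz = FALSE)
  expect_equal(res$decisions$ETT@geometricCategory, "Borderline")
  expect_lt(abs(res$decisions$ETT@dVerticalMm - 20), 1.5)
  expect_equal(res$decisions$ETT@finalLabel, "ETT_Borderline")
  expect_equal(res$decisions$CVC@geometricCategory, "Normal")
  expect_equal(res$decisions$CVC@finalLabel, "CVC_Normal")
  expect_null(res$decisions$NGT)             # no NGT channel content
})
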