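test_that("findComponents handles the basic block cases", {
  expect_equal(nrow(findComponents(matrix(0L, 16, 16))), 0L)

  m <- matrix(0L, 40, 40)
  m[21:23, 11:13] <- 1L          # 3x3 block, rows 21..23 -> y 20..22, x 10..12
  cc <- findComponents(m)
  expect_equal(cc$pixelCount, 9)
  expect_equal(cc$centroidX, 11)
  expect_equal(cc$centroidY, 21)
  expect_false(cc$touchesBorder)

  m2 <- matrix(0L, 40, 40)
  m2[30:31, 30:31] <- 1L         # 4 px
  m2[5:7, 5:7] <- 1L             # 9 px
  cc2 <- findComponents(m2)
  expect_equal(nrow(cc2), 2L)
  expect_equal(cc2$pixelCount, c(9, 4))  # largest first
})

test_that("thin diagonal chains stay one component (8-connectivity)", {
  m <- matrix(0L, 30, 30)
  for (i in 1:20) m[i, i] <- 1L
  expect_equal(nrow(findComponents(m)), 1L)
})

test_that("non-binary masks are rejected", {
  expect_error(findComponents(matrix(c(0L, 2L), 2, 2)), "binary")
  expect_error(visibleLineLengthMm(matrix(0.5, 3, 3), ImageMeta(3, 3, 1)), "binary")
})

test_that("component pixel counts conserve the foreground total", {
  set.seed(7)
  for (k in 1:40) {
    m <- randomMask(sample(5:48, 1), sample(5:48, 1), runif(1, 0.05, 0.6))
    cc <- findComponents(m)
    expect_equal(sum(cc$pixelCount), sum(m))
  }
})

test_that("labelling agrees with a stack-based flood-fill oracle", {
  set.seed(101)
  for (k in 1:150) {
    m <- randomMask(sample(4:64, 1), sample(4:64, 1), runif(1, 0.05, 0.7))
    got <- findComponents(m)
    want <- oracleComponentStats(oracleFloodFill(m))
    expect_equal(got, want)
  }
})

test_that("tip selection prefers the component nearest the reference landmark", {
  meta <- ImageMeta(100, 100, 1)
  m <- matrix(0L, 100, 100)
  m[21:23, 21:23] <- 1L          # centroid (21, 21), near the reference
  m[61:62, 61:62] <- 1L          # centroid (60.5, 60.5)
  comps <- findComponents(m)
  ref <- c(25, 30)
  det <- selectTip(comps, "CVC", reference = ref, meta = meta)
  expect_equal(unname(det$tip), c(21, 21))
  expect_equal(det$selectionRule, "nearest_to_landmark")

  # no reference: largest wins; exhaustive check against enumeration
  det2 <- selectTip(comps, "CVC")
  best <- comps[which.max(comps$pixelCount), ]
  expect_equal(unname(det2$tip), c(best$centroidX, best$centroidY))
  expect_equal(det2$selectionRule, "largest")

  expect_null(selectTip(findComponents(matrix(0L, 5, 5)), "ETT"))
})

test_that("visible line length matches closed forms for straight chains", {
  m <- matrix(0L, 20, 120)
  m[10, 5:105] <- 1L             # 101 px horizontal
  expect_equal(visibleLineLengthMm(m, ImageMeta(120, 20, 1)), 100)

  d <- matrix(0L, 60, 60)
  for (i in 1:51) d[i, i] <- 1L  # 51 px staircase
  expect_equal(visibleLineLengthMm(d, ImageMeta(60, 60, 1)), 50 * sqrt(2))

  expect_equal(visibleLineLengthMm(matrix(0L, 8, 8), ImageMeta(8, 8, 1)), 0)
})

test_that("rasterized straight segments measure within 8% at any angle", {
  meta <- ImageMeta(220, 220, 1)
  set.seed(5)
  angles <- c(runif(10, 0, 90), 22.5, 30, 45, 67.5)
  for (ang in angles) {
    th <- ang * pi / 180
    L <- runif(1, 40, 150)
    p0 <- c(25, 25)
    p1 <- p0 + L * c(cos(th), sin(th))
    poly <- cbind(seq(p0[1], p1[1], length.out = 400),
                  seq(p0[2], p1[2], length.out = 400))
    got <- visibleLineLengthMm(rasterizePolyline(poly, 220, 220, 3), meta)
    expect_lt(abs(got - L) / L, 0.08)
  }
})

test_that("incomplete-imaging predicate follows its truth table", {
  meta <- ImageMeta(60, 60, 1)
  # line running off the bottom edge, no tip blob -> incompletely imaged
  off <- matrix(0L, 60, 60); off[40:60, 30] <- 1L
  expect_true(isIncompletelyImaged(off, NULL))
  expect_true(isIncompletelyImaged(off, findComponents(matrix(0L, 60, 60))))
  # fully interior line with an interior tip -> complete
  int <- matrix(0L, 60, 60); int[10:40, 30] <- 1L
  tip <- matrix(0L, 60, 60); tip[40:42, 29:31] <- 1L
  expect_false(isIncompletelyImaged(int, findComponents(tip)))
  # interior line but tip only at the border -> incomplete
  btip <- matrix(0L, 60, 60); btip[1, 1:2] <- 1L
  expect_true(isIncompletelyImaged(off, findComponents(btip)))
  # blank channel: absent tube, not incompletely imaged
  expect_false(isIncompletelyImaged(matrix(0L, 60, 60), NULL))
})

test_that("NGT tip recovery finds the distal end and advancement past the GEJ", {
  meta <- ImageMeta(120, 200, 1)
  # vertical tube from the top edge through a "junction" at y = 120 down to y = 180
  poly <- cbind(rep(60, 200), seq(0, 180, length.out = 200))
  mk <- rasterizePolyline(poly, 120, 200, 3)
  carina <- c(58, 60); gej <- c(60, 120)
  info <- ngtTipFromLine(mk, meta, carina = carina, gej = gej)
  expect_lt(abs(info$tip[["y"]] - 180), 3)   # thinning erodes ends by ~half thickness
  expect_lt(abs(info$dBeyondMm - 60), 4)
  expect_false(info$tipOnBorder)
  expect_false(info$usedFallback)

  # without a carina: lowermost end fallback, flagged
  info2 <- ngtTipFromLine(mk, meta, gej = gej)
  expect_true(info2$usedFallback)
  expect_lt(abs(info2$tip[["y"]] - 180), 3)

  expect_null(ngtTipFromLine(matrix(0L, 200, 120), meta))
})
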