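# Synthetic radiograph-shaped fixtures: plausible landmark geometry, tube
# polylines whose tip positions realize a requested geometric category,
# rasterized mask channels, binormal classifier scores at a target AUC, and
# Gaussian reader noise on landmarks. No photorealism is attempted -- only
# the inputs the assessment pipeline consumes.

#' SimConfig: parameters of the synthetic cohort generator
#'
#' Defaults emulate the composition of a 303-patient ICU cohort: tube
#' presence rates ETT 178/303, CVC 148/303, NGT 39/303; category mixtures
#' ETT 140/33/5, CVC 98/27/12 plus 11 Swan-Ganz, NGT 20/4/2/13 (the last
#' being incompletely imaged); ECG-lead subgroup rate 151/303.
#'
#' @slot nImages number of radiographs to simulate
#' @slot width,height image size in pixels
#' @slot spacingMm isotropic pixel spacing, mm/px
#' @slot classMixture named list of per-tube category probabilities
#' @slot tubePresence named numeric of per-tube presence probabilities
#' @slot targetAuc discrimination of the simulated classifier scores
#' @slot landmarkNoiseSdMm per-axis SD of simulated labeler noise, mm
#' @slot ecgFraction fraction of images flagged as having ECG leads
#' @slot lineThicknessPx rasterized line thickness
#' @slot tipRadiusPx rasterized tip disc radius
#' @slot seed base seed; each image uses a substream derived from it by
#'   counter, so changing `nImages` does not perturb earlier images
#' @export
setClass("SimConfig",
  representation(
    nImages = "integer", width = "integer", height = "integer",
    spacingMm = "numeric", classMixture = "list", tubePresence = "numeric",
    targetAuc = "numeric", landmarkNoiseSdMm = "numeric",
    ecgFraction = "numeric", lineThicknessPx = "numeric",
    tipRadiusPx = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@width < 192L || object@height < 224L)
    msg <- c(msg, "image too small to honor the landmark placement bands (need >= 192 x 224)")
  if (object@spacingMm <= 0) msg <- c(msg, "spacingMm must be positive")
  for (tb in c("ETT", "CVC", "NGT")) {
    p <- object@classMixture[[tb]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-8)
      msg <- c(msg, paste0("classMixture$", tb, " must sum to 1"))
  }
  if (!(object@targetAuc > 0.5 && object@targetAuc < 1))
    msg <- c(msg, "targetAuc must lie in (0.5, 1)")
  if (object@landmarkNoiseSdMm < 0) msg <- c(msg, "landmarkNoiseSdMm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nImages number of images (default 303, the emulated cohort size)
#' @param width,height image size in pixels (default 512 x 512)
#' @param spacingMm isotropic pixel spacing (default 0.7 mm/px, a typical
#'   downsampled chest radiograph scale giving a ~36 cm field)
#' @param classMixture per-tube category probabilities; defaults are the
#'   cohort proportions described above
#' @param tubePresence per-tube presence probabilities
#' @param targetAuc score discrimination (default 0.9)
#' @param landmarkNoiseSdMm labeler noise SD per axis (default 3 mm)
#' @param ecgFraction ECG-lead subgroup rate (default 151/303)
#' @param lineThicknessPx,tipRadiusPx rasterization sizes in pixels
#' @param seed base integer seed
#' @return a [SimConfig-class]
#' @export
SimConfig <- function(nImages = 303L, width = 512L, height = 512L,
                      spacingMm = 0.7,
                      classMixture = list(
                        ETT = c(Normal = 140, Borderline = 33, Abnormal = 5) / 178,
                        CVC = c(Normal = 98, Borderline = 27, Abnormal = 12,
                                SwanGanz = 11) / 148,
                        NGT = c(Normal = 20, Borderline = 4, Abnormal = 2,
                                IncompletelyImaged = 13) / 39
                      ),
                      tubePresence = c(ETT = 178, CVC = 148, NGT = 39) / 303,
                      targetAuc = 0.9, landmarkNoiseSdMm = 3,
                      ecgFraction = 151 / 303,
                      lineThicknessPx = 3, tipRadiusPx = 3, seed = 1L) {
  new("SimConfig",
    nImages = as.integer(nImages), width = as.integer(width),
    height = as.integer(height), spacingMm = as.numeric(spacingMm),
    classMixture = classMixture, tubePresence = tubePresence,
    targetAuc = as.numeric(targetAuc),
    landmarkNoiseSdMm = as.numeric(landmarkNoiseSdMm),
    ecgFraction = as.numeric(ecgFraction),
    lineThicknessPx = as.numeric(lineThicknessPx),
    tipRadiusPx = as.numeric(tipRadiusPx), seed = as.integer(seed)
  )
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d images, %d x %d px @ %.3g mm/px, target AUC %.2f, seed %d\n",
    object@nImages, object@width, object@height, object@spacingMm,
    object@targetAuc, object@seed))
})

# substream seed for image i: deterministic, independent of nImages, < 2^31
.imageSeed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729 +
                as.numeric(salt) * 15485863) %% 2147483647)
}

.metaFor <- function(cfg, i) {
  ImageMeta(cfg@width, cfg@height, cfg@spacingMm,
            imageId = sprintf("sim%04d", i))
}

#' Sample a plausible landmark configuration
#'
#' The carina is placed in a central band of the upper chest, the cavoatrial
#' junction below and to the right of it by a jittered metric offset, and the
#' gastro-esophageal junction in the lower image region; all strictly
#' in-bounds, with the carina always cranial to the cavoatrial junction.
#' Draws from the current RNG state.
#'
#' @param cfg a [SimConfig-class]
#' @return a [LandmarkSet-class]
#' @export
sampleAnatomy <- function(cfg) {
  W <- cfg@width; H <- cfg@height; sp <- cfg@spacingMm
  carina <- c(stats::runif(1, 0.45, 0.55) * W, stats::runif(1, 0.26, 0.32) * H)
  caj <- carina + c(stats::runif(1, 30, 55) / sp, stats::runif(1, 40, 65) / sp)
  gej <- c(stats::runif(1, 0.42, 0.48) * W, stats::runif(1, 0.66, 0.72) * H)
  pts <- rbind(carina, caj, gej)
  if (any(pts[, 1] < 0) || any(pts[, 1] >= W) || any(pts[, 2] < 0) || any(pts[, 2] >= H))
    stop("image too small to honor the landmark placement bands")
  LandmarkSet(carina = carina, cavoatrialJunction = caj, geJunction = gej)
}

# quadratic Bezier sampled densely (n points)
.bezier <- function(p0, p1, p2, n = 400L) {
  t <- seq(0, 1, length.out = n)
  cbind(
    (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
    (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
  )
}

# circular-arc continuation from a start point: initial heading phi0
# (radians; 0 = +x, pi/2 = +y i.e. caudal), turning left with radius R px,
# total arc length sPx
.arcPath <- function(start, phi0, R, sPx, step = 0.5) {
  s <- seq(0, sPx, by = step)
  phi <- phi0 + s / R
  cbind(start[1] + R * (sin(phi) - sin(phi0)),
        start[2] - R * (cos(phi) - cos(phi0)))
}

#' Sample a tube whose tip realizes a requested geometric category
#'
#' Draws a smooth polyline from an entry edge to a tip point whose distance
#' to the tube's reference landmark falls inside the requested category's
#' band, with a safety margin of a few millimetres from the band edges so
#' rasterization and skeleton measurement cannot flip the category.
#'
#' @param tubeKind `"ETT"`, `"CVC"` or `"NGT"`
#' @param category target geometric category (for CVC, `"SwanGanz"` draws a
#'   catheter whose tip may sit below the junction but which is labeled
#'   Normal by the Swan-Ganz convention)
#' @param landmarks a [LandmarkSet-class] from [sampleAnatomy()]
#' @param cfg a [SimConfig-class]
#' @return list with `polyline` (n x 2 matrix of pixel points), `tip`
#'   (`c(x, y)`), and the analytic distance realized (`dMm`, signed mm above
#'   the reference for ETT/CVC; arc mm beyond the GE junction for NGT, with
#'   `NA` for abnormal/incomplete configurations)
#' @export
sampleTube <- function(tubeKind = c("ETT", "CVC", "NGT"), category,
                       landmarks, cfg) {
  tubeKind <- match.arg(tubeKind)
  sp <- cfg@spacingMm; W <- cfg@width; H <- cfg@height
  if (tubeKind == "ETT") {
    carina <- landmark(landmarks, "carina")
    if (is.null(carina)) stop("ETT sampling requires the carina landmark")
    maxHigh <- min(88, (carina[2] - 6) * sp)
    d <- switch(category,
      Normal = stats::runif(1, 37, 68),
      Borderline = if (stats::runif(1) < 0.5) stats::runif(1, 5, 32)
                   else stats::runif(1, 72, maxHigh),
      Abnormal = stats::runif(1, -40, -3),
      stop("impossible ETT category: ", category)
    )
    tip <- c(carina[1] + stats::runif(1, -6, 6), carina[2] - d / sp)
    entry <- c(carina[1] + stats::runif(1, -8, 8), 0)
    poly <- .bezier(entry, c(tip[1], tip[2] / 2), tip, n = 200L)
    return(list(polyline = poly, tip = tip, dMm = d))
  }
  if (tubeKind == "CVC") {
    caj <- landmark(landmarks, "cavoatrial_junction")
    if (is.null(caj)) stop("CVC sampling requires the cavoatrial junction landmark")
    d <- switch(category,
      Normal = stats::runif(1, 3, 55),
      Borderline = stats::runif(1, -23, -3),
      Abnormal = stats::runif(1, -60, -27),
      SwanGanz = stats::runif(1, -30, 30),
      stop("impossible CVC category: ", category)
    )
    tip <- c(caj[1] + stats::runif(1, -8, 8), caj[2] - d / sp)
    side <- sample(c("L", "R"), 1)
    entry <- if (side == "L") c(0, stats::runif(1, 0.10, 0.18) * H)
             else c(W - 1, stats::runif(1, 0.10, 0.18) * H)
    poly <- .bezier(entry, c(tip[1], entry[2]), tip, n = 300L)
    return(list(polyline = poly, tip = tip, dMm = d))
  }
  # NGT: enters at the top near the carina column (esophageal course), runs
  # past the GE junction, then curls within the stomach region on a circular
  # arc; the tip is cut at the requested advancement beyond the junction.
  carina <- landmark(landmarks, "carina")
  gej <- landmark(landmarks, "ge_junction")
  if (is.null(gej)) stop("NGT sampling requires the GE junction landmark")
  if (category == "IncompletelyImaged") {
    # short visible segment running off the bottom edge; the tip is off-film
    lenPx <- stats::runif(1, 40, 80) / sp
    x0 <- stats::runif(1, 0.30, 0.60) * W
    top <- c(x0 + stats::runif(1, -10, 10), H - 1 - lenPx)
    bottom <- c(x0, H - 1)
    poly <- .bezier(top, c((top[1] + bottom[1]) / 2 + 5, (top[2] + bottom[2]) / 2),
                    bottom, n = 150L)
    return(list(polyline = poly, tip = bottom, dMm = NA_real_))
  }
  entry <- c(carina[1] + stats::runif(1, 6, 14), 0)
  ctrl <- c(carina[1] + stats::runif(1, 10, 18), carina[2])
  descent <- .bezier(entry, ctrl, gej, n = 500L)
  if (category == "Abnormal") {
    # tip ends above the GE junction, still within the esophageal course
    dAbove <- stats::runif(1, 30, 80)
    cut <- which(descent[, 2] >= gej[2] - dAbove / sp)[1]
    poly <- descent[seq_len(max(cut, 2L)), , drop = FALSE]
    return(list(polyline = poly, tip = poly[nrow(poly), ], dMm = NA_real_))
  }
  dBeyond <- switch(category,
    Normal = stats::runif(1, 115, 165),
    Borderline = stats::runif(1, 8, 88),
    stop("impossible NGT category: ", category)
  )
  R <- 85  # curl radius: large enough that stomach-curled tips stay caudal
  curl <- .arcPath(gej, phi0 = pi / 2 + stats::runif(1, -0.05, 0.05),
                   R = R, sPx = dBeyond / sp)
  poly <- rbind(descent, curl[-1, , drop = FALSE])
  list(polyline = poly, tip = curl[nrow(curl), ], dMm = dBeyond)
}

#' Rasterize a polyline into a binary mask
#'
#' Stamps a disc of diameter `thicknessPx` along a densely resampled
#' polyline; out-of-bounds samples are clipped (a polyline may legitimately
#' exit the field).
#'
#' @param polyline n x 2 matrix of pixel points `(x, y)`
#' @param width,height mask size
#' @param thicknessPx line thickness in pixels
#' @return binary integer matrix
#' @export
rasterizePolyline <- function(polyline, width, height, thicknessPx = 3) {
  m <- matrix(0L, height, width)
  if (is.null(polyline) || nrow(polyline) < 1L) return(m)
  # resample to ~0.4 px steps so thin lines have no gaps
  seg <- sqrt(diff(polyline[, 1])^2 + diff(polyline[, 2])^2)
  cum <- c(0, cumsum(seg))
  if (cum[length(cum)] > 0) {
    s <- seq(0, cum[length(cum)], by = 0.4)
    xs <- stats::approx(cum, polyline[, 1], xout = s)$y
    ys <- stats::approx(cum, polyline[, 2], xout = s)$y
  } else {
    xs <- polyline[1, 1]; ys <- polyline[1, 2]
  }
  r <- thicknessPx / 2
  off <- expand.grid(dx = seq(-ceiling(r), ceiling(r)),
                     dy = seq(-ceiling(r), ceiling(r)))
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 1e-9, , drop = FALSE]
  px <- as.vector(outer(round(xs), off$dx, `+`))
  py <- as.vector(outer(round(ys), off$dy, `+`))
  ok <- px >= 0 & px < width & py >= 0 & py < height
  m[cbind(py[ok] + 1L, px[ok] + 1L)] <- 1L
  m
}

#' Rasterize a disc (tip blob) into a binary mask
#'
#' @param center `c(x, y)` pixel point
#' @param width,height mask size
#' @param radiusPx disc radius
#' @return binary integer matrix
#' @export
rasterizeDisc <- function(center, width, height, radiusPx = 3) {
  m <- matrix(0L, height, width)
  off <- expand.grid(dx = seq(-ceiling(radiusPx), ceiling(radiusPx)),
                     dy = seq(-ceiling(radiusPx), ceiling(radiusPx)))
  off <- off[off$dx^2 + off$dy^2 <= radiusPx^2 + 1e-9, , drop = FALSE]
  px <- round(center[1]) + off$dx
  py <- round(center[2]) + off$dy
  ok <- px >= 0 & px < width & py >= 0 & py < height
  m[cbind(py[ok] + 1L, px[ok] + 1L)] <- 1L
  m
}

#' Sample binormal classifier scores for one radiograph
#'
#' Each true label's latent score is Normal(mu, 1) with
#' `mu = sqrt(2) * qnorm(targetAuc)`; competing labels draw Normal(0, 1);
#' both are squashed through the logistic function into `[0, 1]`, which
#' leaves the AUC unchanged (it is rank-based).
#'
#' @param truthRow list/one-row data.frame with `ETT`, `NGT`, `CVC`
#'   categories (or `NA`) and logical `swanGanz`
#' @param targetAuc target one-vs-rest AUC in `(0.5, 1)`
#' @return a [ClassScores-class]
#' @export
sampleScores <- function(truthRow, targetAuc = 0.9) {
  mu <- sqrt(2) * stats::qnorm(targetAuc)
  s <- stats::setNames(numeric(length(RANZCR_LABELS)), RANZCR_LABELS)
  for (lb in RANZCR_LABELS) {
    isPos <- if (lb == "SwanGanzPresent") {
      isTRUE(truthRow$swanGanz)
    } else {
      tube <- sub("_.*", "", lb)
      cat <- sub("^[A-Z]+_", "", lb)
      !is.na(truthRow[[tube]]) && truthRow[[tube]] == cat
    }
    s[lb] <- stats::plogis(stats::rnorm(1, mean = if (isPos) mu else 0, sd = 1))
  }
  ClassScores(s)
}

#' Add Gaussian reader noise to landmarks
#'
#' Displaces each present point landmark by isotropic Gaussian noise with the
#' given per-axis SD in millimetres (converted to pixels through the image
#' spacing) and clips the result in-bounds, emulating a human labeler.
#'
#' @param landmarks a [LandmarkSet-class]
#' @param sdMm per-axis noise SD, mm
#' @param meta an [ImageMeta-class]
#' @return a noisy [LandmarkSet-class]
#' @export
corruptLandmarks <- function(landmarks, sdMm, meta) {
  stopifnot(is(landmarks, "LandmarkSet"), is(meta, "ImageMeta"))
  if (sdMm == 0) return(landmarks)
  pts <- landmarks@points
  for (nm in names(pts)) {
    p <- pts[[nm]]
    p[1] <- min(max(p[1] + stats::rnorm(1, 0, sdMm / meta@spacingCol), 0), meta@width - 1)
    p[2] <- min(max(p[2] + stats::rnorm(1, 0, sdMm / meta@spacingRow), 0), meta@height - 1)
    pts[[nm]] <- p
  }
  out <- landmarks
  out@points <- pts
  out
}

#' Simulate one synthetic radiograph
#'
#' Draws the image's anatomy, tube presence and categories, rasterizes the
#' mask channels and samples classifier scores, all from a per-image seed
#' substream derived from the config seed by counter.
#'
#' @param cfg a [SimConfig-class]
#' @param i image index (1-based)
#' @return list with `meta`, `landmarks`, `masks` (a [MaskChannelSet-class]),
#'   `scores` (a [ClassScores-class]), `truth` (one-row data.frame with
#'   `imageId`, `ETT`, `NGT`, `CVC`, `swanGanz`, `ecgLeads`), `tips` (list of
#'   analytic tip points) and `dMm` (list of analytic distances)
#' @export
simulateImage <- function(cfg, i) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(.imageSeed(cfg@seed, i))
  meta <- .metaFor(cfg, i)
  lm <- sampleAnatomy(cfg)
  present <- stats::runif(3) < cfg@tubePresence[c("ETT", "CVC", "NGT")]
  names(present) <- c("ETT", "CVC", "NGT")
  pick <- function(tube) {
    p <- cfg@classMixture[[tube]]
    sample(names(p), 1, prob = p)
  }
  ett <- if (present["ETT"]) pick("ETT") else NA_character_
  cvcRaw <- if (present["CVC"]) pick("CVC") else NA_character_
  ngt <- if (present["NGT"]) pick("NGT") else NA_character_
  swan <- identical(cvcRaw, "SwanGanz")
  cvc <- if (swan) "Normal" else cvcRaw  # Swan-Ganz is Normal by convention
  tips <- list(); dMm <- list()
  chans <- list(ngtLine = NULL, cvcLine = NULL, cvcTip = NULL, ettTip = NULL)
  if (present["ETT"]) {
    tb <- sampleTube("ETT", ett, lm, cfg)
    chans$ettTip <- rasterizeDisc(tb$tip, cfg@width, cfg@height, cfg@tipRadiusPx)
    tips$ETT <- tb$tip; dMm$ETT <- tb$dMm
  }
  if (present["CVC"]) {
    tb <- sampleTube("CVC", cvcRaw, lm, cfg)
    chans$cvcLine <- rasterizePolyline(tb$polyline, cfg@width, cfg@height,
                                       cfg@lineThicknessPx)
    chans$cvcTip <- rasterizeDisc(tb$tip, cfg@width, cfg@height, cfg@tipRadiusPx)
    tips$CVC <- tb$tip; dMm$CVC <- tb$dMm
  }
  if (present["NGT"]) {
    tb <- sampleTube("NGT", ngt, lm, cfg)
    chans$ngtLine <- rasterizePolyline(tb$polyline, cfg@width, cfg@height,
                                       cfg@lineThicknessPx)
    tips$NGT <- tb$tip; dMm$NGT <- tb$dMm
  }
  masks <- MaskChannelSet(meta, ngtLine = chans$ngtLine, cvcLine = chans$cvcLine,
                          cvcTip = chans$cvcTip, ettTip = chans$ettTip)
  truth <- data.frame(
    imageId = meta@imageId, ETT = ett, NGT = ngt, CVC = cvc,
    swanGanz = swan, ecgLeads = stats::runif(1) < cfg@ecgFraction,
    stringsAsFactors = FALSE
  )
  scores <- sampleScores(truth, cfg@targetAuc)
  list(meta = meta, landmarks = lm, masks = masks, scores = scores,
       truth = truth, tips = tips, dMm = dMm)
}

#' Simulate a synthetic cohort
#'
#' Runs [simulateImage()] for `nImages` images. Mask channels are large, so
#' they are kept only on request; truth, landmarks and scores are always
#' returned.
#'
#' @param cfg a [SimConfig-class]
#' @param keepMasks retain the [MaskChannelSet-class] per image (memory-heavy)
#' @return list with `truth` (data.frame), `scores` (matrix over
#'   [RANZCR_LABELS]), `landmarks` (list of [LandmarkSet-class]), `metas`
#'   (list of [ImageMeta-class]), and `masks` (list or `NULL`)
#' @export
simulateCohort <- function(cfg, keepMasks = FALSE) {
  stopifnot(is(cfg, "SimConfig"))
  truth <- vector("list", cfg@nImages)
  scores <- matrix(NA_real_, cfg@nImages, length(RANZCR_LABELS),
                   dimnames = list(NULL, RANZCR_LABELS))
  lms <- vector("list", cfg@nImages)
  metas <- vector("list", cfg@nImages)
  masks <- if (keepMasks) vector("list", cfg@nImages)
  for (i in seq_len(cfg@nImages)) {
    im <- simulateImage(cfg, i)
    truth[[i]] <- im$truth
    scores[i, ] <- scoreVector(im$scores)
    lms[[i]] <- im$landmarks
    metas[[i]] <- im$meta
    if (keepMasks) masks[[i]] <- im$masks
  }
  list(truth = do.call(rbind, truth), scores = scores, landmarks = lms,
       metas = metas, masks = masks)
}
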