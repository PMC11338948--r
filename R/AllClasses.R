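#' @import methods
NULL

#' RANZCR-CLiP label set
#'
#' The eleven multilabel targets used for tube and line position assessment:
#' three position categories for endotracheal tubes (ETT) and central venous
#' catheters (CVC), four for nasogastric tubes (NGT, which can additionally be
#' incompletely imaged), and a Swan-Ganz presence label.
#'
#' @format Character vector of length 11.
#' @export
RANZCR_LABELS <- c(
  "ETT_Normal", "ETT_Borderline", "ETT_Abnormal",
  "NGT_Normal", "NGT_Borderline", "NGT_Abnormal", "NGT_IncompletelyImaged",
  "CVC_Normal", "CVC_Borderline", "CVC_Abnormal",
  "SwanGanzPresent"
)

#' Label groups per tube kind
#'
#' Mapping from tube kind to its position labels, used for group-averaged AUCs
#' and for the rule-based score correction (which only permutes scores within
#' one tube's group).
#'
#' @format Named list of character vectors.
#' @export
TUBE_LABEL_GROUPS <- list(
  ETT = c("ETT_Normal", "ETT_Borderline", "ETT_Abnormal"),
  NGT = c("NGT_Normal", "NGT_Borderline", "NGT_Abnormal", "NGT_IncompletelyImaged"),
  CVC = c("CVC_Normal", "CVC_Borderline", "CVC_Abnormal")
)

.LANDMARK_NAMES <- c("carina", "cavoatrial_junction", "ge_junction")
.MASK_CHANNELS <- c("ngt_line", "cvc_line", "cvc_tip", "ett_tip")
.CATEGORY_RANK <- c(Normal = 1L, Borderline = 2L, Abnormal = 3L)

#' ImageMeta: image dimensions and pixel spacing
#'
#' Carries the pixel grid size and the physical pixel spacing in mm per pixel
#' for one radiograph. All metric distances in the package are derived from
#' this object; spacing is mandatory because the position criteria are
#' denominated in centimetres. Row spacing applies to the vertical (y) axis,
#' column spacing to the horizontal (x) axis; anisotropic spacing is supported.
#'
#' @slot width image width in pixels
#' @slot height image height in pixels
#' @slot spacingRow mm per pixel along image rows (vertical direction)
#' @slot spacingCol mm per pixel along image columns (horizontal direction)
#' @slot imageId opaque image identifier used in error messages and reports
#' @export
setClass("ImageMeta",
  representation(
    width = "integer", height = "integer",
    spacingRow = "numeric", spacingCol = "numeric",
    imageId = "character"
  )
)

setValidity("ImageMeta", function(object) {
  msg <- character()
  if (length(object@width) != 1L || is.na(object@width) || object@width <= 0L)
    msg <- c(msg, "width must be a single positive integer")
  if (length(object@height) != 1L || is.na(object@height) || object@height <= 0L)
    msg <- c(msg, "height must be a single positive integer")
  if (length(object@spacingRow) != 1L || is.na(object@spacingRow) || object@spacingRow <= 0)
    msg <- c(msg, "spacingRow must be a single positive number (mm/px)")
  if (length(object@spacingCol) != 1L || is.na(object@spacingCol) || object@spacingCol <= 0)
    msg <- c(msg, "spacingCol must be a single positive number (mm/px)")
  if (length(object@imageId) != 1L) msg <- c(msg, "imageId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageMeta
#'
#' @param width,height image size in pixels
#' @param spacingRow mm per pixel vertically; if `spacingCol` is missing it is
#'   reused for both axes (single-valued spacing)
#' @param spacingCol mm per pixel horizontally
#' @param imageId image identifier
#' @return an [ImageMeta-class] object
#' @examples
#' ImageMeta(512, 512, spacingRow = 0.7, imageId = "img001")
#' @export
ImageMeta <- function(width, height, spacingRow, spacingCol = spacingRow,
                      imageId = "unknown") {
  if (missing(spacingRow) || is.null(spacingRow) || !length(spacingRow))
    stop("pixel spacing is required for image '", imageId,
         "': position rules are metric and cannot run without mm/px")
  new("ImageMeta",
    width = as.integer(width), height = as.integer(height),
    spacingRow = as.numeric(spacingRow), spacingCol = as.numeric(spacingCol),
    imageId = as.character(imageId)
  )
}

setMethod("show", "ImageMeta", function(object) {
  cat(sprintf(
    "ImageMeta '%s': %d x %d px, spacing %.4g x %.4g mm/px (row x col)\n",
    object@imageId, object@width, object@height,
    object@spacingRow, object@spacingCol
  ))
})

#' LandmarkSet: anatomical reference points for one radiograph
#'
#' Holds the pixel coordinates of the anatomical landmarks the position rules
#' are referred to: the carina (ETT reference), the cavoatrial junction (CVC
#' reference) and the gastro-esophageal junction (NGT reference), plus two
#' optional vertical levels (T1 and the upper margin of the aortic arch) used
#' by the corresponding optional rule clauses. Any landmark may be absent;
#' rules requiring an absent landmark are skipped, never guessed.
#'
#' Coordinates follow the raster convention: 0-based, origin at the top-left,
#' x increasing rightward, y increasing downward, so "above"/"cranial" means
#' smaller y.
#'
#' @slot points named list; each present entry is `c(x = , y = )` in pixels
#' @slot t1LevelY optional pixel row of the T1 vertebral level (numeric(0) if absent)
#' @slot aorticArchUpperY optional pixel row of the upper aortic arch margin
#' @export
setClass("LandmarkSet",
  representation(points = "list", t1LevelY = "numeric", aorticArchUpperY = "numeric")
)

setValidity("LandmarkSet", function(object) {
  msg <- character()
  bad <- setdiff(names(object@points), .LANDMARK_NAMES)
  if (length(bad)) msg <- c(msg, paste0("unknown landmark name(s): ", paste(bad, collapse = ", ")))
  for (nm in names(object@points)) {
    p <- object@points[[nm]]
    if (!is.numeric(p) || length(p) != 2L || anyNA(p))
      msg <- c(msg, paste0("landmark '", nm, "' must be c(x, y)"))
  }
  if (length(object@t1LevelY) > 1L) msg <- c(msg, "t1LevelY must be length 0 or 1")
  if (length(object@aorticArchUpperY) > 1L) msg <- c(msg, "aorticArchUpperY must be length 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a LandmarkSet
#'
#' @param carina,cavoatrialJunction,geJunction optional `c(x, y)` pixel
#'   coordinates (0-based)
#' @param t1LevelY,aorticArchUpperY optional pixel rows of the T1 level and the
#'   upper aortic arch margin
#' @return a [LandmarkSet-class]
#' @examples
#' LandmarkSet(carina = c(250, 150), cavoatrialJunction = c(310, 230))
#' @export
LandmarkSet <- function(carina = NULL, cavoatrialJunction = NULL, geJunction = NULL,
                        t1LevelY = NULL, aorticArchUpperY = NULL) {
  pts <- list()
  if (!is.null(carina)) pts$carina <- c(x = carina[[1]], y = carina[[2]])
  if (!is.null(cavoatrialJunction))
    pts$cavoatrial_junction <- c(x = cavoatrialJunction[[1]], y = cavoatrialJunction[[2]])
  if (!is.null(geJunction)) pts$ge_junction <- c(x = geJunction[[1]], y = geJunction[[2]])
  new("LandmarkSet",
    points = pts,
    t1LevelY = as.numeric(t1LevelY %||% numeric(0)),
    aorticArchUpperY = as.numeric(aorticArchUpperY %||% numeric(0))
  )
}

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet with", length(object@points), "point landmark(s)\n")
  for (nm in names(object@points)) {
    p <- object@points[[nm]]
    cat(sprintf("  %-20s (%.1f, %.1f)\n", nm, p[[1]], p[[2]]))
  }
  if (length(object@t1LevelY)) cat(sprintf("  t1LevelY            y = %.1f\n", object@t1LevelY))
  if (length(object@aorticArchUpperY))
    cat(sprintf("  aorticArchUpperY    y = %.1f\n", object@aorticArchUpperY))
})

#' Access a landmark point
#'
#' @param x a [LandmarkSet-class]
#' @param name one of `"carina"`, `"cavoatrial_junction"`, `"ge_junction"`
#' @return `c(x, y)` in pixels, or `NULL` when the landmark is absent
#' @export
landmark <- function(x, name) {
  stopifnot(is(x, "LandmarkSet"))
  if (!name %in% .LANDMARK_NAMES) stop("unknown landmark name: ", name)
  x@points[[name]]
}

#' Test landmark presence
#' @param x a [LandmarkSet-class]
#' @param name landmark name
#' @return logical
#' @export
hasLandmark <- function(x, name) !is.null(landmark(x, name))

#' MaskChannelSet: per-class binary segmentation masks for one radiograph
#'
#' The four class-separated mask channels produced by the segmentation stage:
#' NGT line, CVC line, CVC tip and ETT tip (the ETT line and NGT tip channels
#' are not part of the channel scheme; the NGT tip is recovered from the line
#' skeleton). Channels are stored as integer matrices in `{0, 1}` with
#' `height` rows and `width` columns, indexed `[row, col]` (y, x).
#'
#' @slot channels named list of binary integer matrices, one per channel in
#'   `c("ngt_line", "cvc_line", "cvc_tip", "ett_tip")`
#' @slot meta the shared [ImageMeta-class]
#' @export
setClass("MaskChannelSet", representation(channels = "list", meta = "ImageMeta"))

setValidity("MaskChannelSet", function(object) {
  msg <- character()
  if (!setequal(names(object@channels), .MASK_CHANNELS))
    msg <- c(msg, paste0("channels must be exactly: ", paste(.MASK_CHANNELS, collapse = ", ")))
  for (nm in names(object@channels)) {
    ch <- object@channels[[nm]]
    if (!is.matrix(ch)) { msg <- c(msg, paste0(nm, " is not a matrix")); next }
    if (nrow(ch) != object@meta@height || ncol(ch) != object@meta@width)
      msg <- c(msg, paste0(nm, " does not match meta dimensions"))
    if (!all(ch %in% c(0L, 1L)))
      msg <- c(msg, paste0(nm, " contains values outside {0, 1}"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MaskChannelSet
#'
#' @param ngtLine,cvcLine,cvcTip,ettTip binary matrices (`height` rows by
#'   `width` columns); missing channels default to all-zero
#' @param meta an [ImageMeta-class]
#' @return a [MaskChannelSet-class]
#' @export
MaskChannelSet <- function(meta, ngtLine = NULL, cvcLine = NULL,
                           cvcTip = NULL, ettTip = NULL) {
  z <- function(m) if (is.null(m)) matrix(0L, meta@height, meta@width) else
    matrix(as.integer(m), nrow(m), ncol(m))
  new("MaskChannelSet",
    channels = list(
      ngt_line = z(ngtLine), cvc_line = z(cvcLine),
      cvc_tip = z(cvcTip), ett_tip = z(ettTip)
    ),
    meta = meta
  )
}

setMethod("show", "MaskChannelSet", function(object) {
  cat(sprintf("MaskChannelSet '%s' (%d x %d px)\n",
    object@meta@imageId, object@meta@width, object@meta@height))
  for (nm in .MASK_CHANNELS)
    cat(sprintf("  %-10s %d foreground px\n", nm, sum(object@channels[[nm]])))
})

#' Access one mask channel
#' @param x a [MaskChannelSet-class]
#' @param name channel name (`"ngt_line"`, `"cvc_line"`, `"cvc_tip"`, `"ett_tip"`)
#' @return binary integer matrix
#' @export
maskChannel <- function(x, name) {
  stopifnot(is(x, "MaskChannelSet"))
  if (!name %in% .MASK_CHANNELS) stop("unknown mask channel: ", name)
  x@channels[[name]]
}

#' ClassScores: multilabel classifier scores for one radiograph
#'
#' One score in `[0, 1]` per RANZCR-CLiP label. The labels are multilabel
#' sigmoid outputs: scores do not sum to one, neither across nor within tube
#' groups.
#'
#' @slot scores named numeric vector over [RANZCR_LABELS]
#' @export
setClass("ClassScores", representation(scores = "numeric"))

setValidity("ClassScores", function(object) {
  s <- object@scores
  if (!identical(names(s), RANZCR_LABELS))
    return("scores must be named exactly by RANZCR_LABELS, in order")
  if (anyNA(s) || any(s < 0) || any(s > 1))
    return("all scores must lie in [0, 1]")
  TRUE
})

#' Construct ClassScores
#'
#' @param scores named numeric vector; names must cover [RANZCR_LABELS]
#'   (order-free; missing entries are an error)
#' @return a [ClassScores-class]
#' @examples
#' s <- setNames(rep(0.1, 11), RANZCR_LABELS)
#' s["ETT_Normal"] <- 0.9
#' ClassScores(s)
#' @export
ClassScores <- function(scores) {
  if (is(scores, "ClassScores")) return(scores)
  miss <- setdiff(RANZCR_LABELS, names(scores))
  if (length(miss)) stop("missing score(s) for: ", paste(miss, collapse = ", "))
  new("ClassScores", scores = as.numeric(scores[RANZCR_LABELS]) |>
    stats::setNames(RANZCR_LABELS))
}

#' Extract the named score vector
#' @param x a [ClassScores-class]
#' @return named numeric over [RANZCR_LABELS]
#' @export
scoreVector <- function(x) {
  stopifnot(is(x, "ClassScores"))
  x@scores
}

setMethod("show", "ClassScores", function(object) {
  cat("ClassScores:\n")
  print(round(object@scores, 3))
})

#' RuleConfig: thresholds and switches of the position rule engine
#'
#' Encodes the distance criteria used to categorise tube tips. Distances on
#' radiographs are often expressed in posterior-rib units; the engine uses the
#' standard centimetre surrogates: two posterior ribs ~ 3.5 cm (ETT band lower
#' edge), twice that ~ 7 cm (upper edge), four posterior ribs ~ 10 cm (NGT
#' advancement beyond the gastro-esophageal junction).
#'
#' @slot ettMinMm lower edge of the normal ETT tip band above the carina (mm,
#'   default 35)
#' @slot ettMaxMm upper edge of the normal ETT band (mm, default 70)
#' @slot ngtMinMm minimum NGT advancement beyond the GE junction (mm, default 100)
#' @slot raUpperThirdMm depth of the band below the cavoatrial junction treated
#'   as the upper third of the right atrium (mm, default 25). This is an
#'   engineering stand-in: the right atrium has no landmark in the data model.
#' @slot distanceMode `"vertical"` (cranio-caudal separation; default, matching
#'   the above/below phrasing of the criteria) or `"euclidean"`
#' @slot enabledRules rule identifiers the engine may fire; an empty set turns
#'   the correction off entirely (distances are still reported)
#' @slot boundaryInclusiveNormal when TRUE (default) a tip exactly on a band
#'   edge is Normal (the borderline clauses are strict inequalities)
#' @export
setClass("RuleConfig",
  representation(
    ettMinMm = "numeric", ettMaxMm = "numeric", ngtMinMm = "numeric",
    raUpperThirdMm = "numeric", distanceMode = "character",
    enabledRules = "character", boundaryInclusiveNormal = "logical"
  )
)

#' All rule identifiers known to the engine
#' @format character vector
#' @export
ALL_RULES <- c(
  "ETT_BELOW_CARINA", "ETT_T1_HIGH", "ETT_LOW", "ETT_HIGH",
  "NGT_INCOMPLETE", "NGT_ABOVE_GEJ", "NGT_SHORT",
  "SWAN_GANZ_NORMAL", "CVC_BELOW_RA_THIRD", "CVC_BELOW_CAJ", "CVC_ABOVE_ARCH"
)

setValidity("RuleConfig", function(object) {
  msg <- character()
  if (!(object@ettMinMm > 0 && object@ettMinMm < object@ettMaxMm))
    msg <- c(msg, "need 0 < ettMinMm < ettMaxMm")
  if (object@ngtMinMm <= 0) msg <- c(msg, "ngtMinMm must be positive")
  if (object@raUpperThirdMm <= 0) msg <- c(msg, "raUpperThirdMm must be positive")
  if (!object@distanceMode %in% c("vertical", "euclidean"))
    msg <- c(msg, "distanceMode must be 'vertical' or 'euclidean'")
  bad <- setdiff(object@enabledRules, ALL_RULES)
  if (length(bad)) msg <- c(msg, paste0("unknown rule id(s): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a RuleConfig
#'
#' @param ettMinMm,ettMaxMm normal ETT tip band above the carina, mm
#' @param ngtMinMm minimum NGT advancement beyond the GE junction, mm
#' @param raUpperThirdMm band below the cavoatrial junction standing in for the
#'   upper third of the right atrium, mm
#' @param distanceMode `"vertical"` or `"euclidean"`
#' @param enabledRules rule identifiers allowed to fire (default all of
#'   [ALL_RULES]); pass `character(0)` to disable the rule-based correction
#' @param boundaryInclusiveNormal band edges count as Normal when TRUE
#' @return a [RuleConfig-class]
#' @examples
#' RuleConfig()                              # full rule set
#' RuleConfig(enabledRules = character(0))   # correction disabled
#' @export
RuleConfig <- function(ettMinMm = 35, ettMaxMm = 70, ngtMinMm = 100,
                       raUpperThirdMm = 25, distanceMode = "vertical",
                       enabledRules = ALL_RULES,
                       boundaryInclusiveNormal = TRUE) {
  new("RuleConfig",
    ettMinMm = as.numeric(ettMinMm), ettMaxMm = as.numeric(ettMaxMm),
    ngtMinMm = as.numeric(ngtMinMm), raUpperThirdMm = as.numeric(raUpperThirdMm),
    distanceMode = distanceMode, enabledRules = as.character(enabledRules),
    boundaryInclusiveNormal = boundaryInclusiveNormal
  )
}

setMethod("show", "RuleConfig", function(object) {
  cat(sprintf(
    "RuleConfig: ETT band [%g, %g] mm above carina; NGT >= %g mm beyond GEJ;\n",
    object@ettMinMm, object@ettMaxMm, object@ngtMinMm))
  cat(sprintf("  RA upper-third band %g mm below CAJ; distance mode '%s'; %d/%d rules enabled\n",
    object@raUpperThirdMm, object@distanceMode,
    length(object@enabledRules), length(ALL_RULES)))
})

#' RuleDecision: outcome of the rule engine for one tube on one radiograph
#'
#' @slot tubeKind `"ETT"`, `"NGT"` or `"CVC"`
#' @slot geometricCategory `"Normal"`, `"Borderline"`, `"Abnormal"`,
#'   `"IncompletelyImaged"` or `"Indeterminate"` (required landmark absent)
#' @slot firedRules identifiers of the rules that fired
#' @slot dVerticalMm signed cranio-caudal tip-to-landmark distance, mm
#'   (positive = tip cranial to the landmark; `NA` when unavailable)
#' @slot dEuclideanMm straight-line tip-to-landmark distance, mm
#' @slot adjustedScores [ClassScores-class] after the rule-based correction
#' @slot finalLabel the argmax label within the tube's group after correction
#' @export
setClass("RuleDecision",
  representation(
    tubeKind = "character", geometricCategory = "character",
    firedRules = "character", dVerticalMm = "numeric", dEuclideanMm = "numeric",
    adjustedScores = "ClassScores", finalLabel = "character"
  )
)

setMethod("show", "RuleDecision", function(object) {
  cat(sprintf("RuleDecision [%s]: geometry %s; final label %s\n",
    object@tubeKind, object@geometricCategory, object@finalLabel))
  cat(sprintf("  d_vertical = %s mm, d_euclidean = %s mm; fired: %s\n",
    format(round(object@dVerticalMm, 1)), format(round(object@dEuclideanMm, 1)),
    if (length(object@firedRules)) paste(object@firedRules, collapse = ", ") else "(none)"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
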