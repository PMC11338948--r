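# The RANZCR-CLiP position criteria as a deterministic classifier over
# tip-to-landmark distances, and the rule-based correction of multilabel
# classifier scores. Distances are signed mm, positive = tip cranial to
# (above) its reference landmark.
#
# Each clause carries a stable rule identifier; clauses whose identifier is
# not in cfg@enabledRules are skipped, so the same engine expresses both the
# plain pipeline (enabledRules = character(0): distances reported, scores
# untouched) and the full rule-based system.

.ruleOn <- function(cfg, id) id %in% cfg@enabledRules

#' Geometric category of an endotracheal tube tip
#'
#' The ETT tip should sit 3.5-7 cm above the carina (two posterior ribs to
#' twice that, via the ~3.5 cm rib surrogate). At or below the carina -- or at
#' the level of T1 or above, when a T1 level is supplied -- is Abnormal; too
#' low (under 3.5 cm) or too high (over 7 cm) within the airway is Borderline.
#'
#' @param dMm signed distance from tip to carina (mm, positive above), `NA`
#'   when the carina landmark is absent
#' @param t1Above optional flag: tip at the T1 level or above (`NA` when the
#'   T1 level is not annotated; the clause is then skipped)
#' @param cfg a [RuleConfig-class]
#' @return a list with `category` and `fired` (rule identifiers)
#' @examples
#' classifyEtt(20, cfg = RuleConfig())$category   # "Borderline"
#' classifyEtt(50, cfg = RuleConfig())$category   # "Normal"
#' @export
classifyEtt <- function(dMm, t1Above = NA, cfg = RuleConfig()) {
  if (is.na(dMm)) return(list(category = "Indeterminate", fired = character(0)))
  inc <- cfg@boundaryInclusiveNormal
  if (.ruleOn(cfg, "ETT_BELOW_CARINA") && dMm <= 0)
    return(list(category = "Abnormal", fired = "ETT_BELOW_CARINA"))
  if (.ruleOn(cfg, "ETT_T1_HIGH") && isTRUE(t1Above))
    return(list(category = "Abnormal", fired = "ETT_T1_HIGH"))
  low <- if (inc) dMm < cfg@ettMinMm else dMm <= cfg@ettMinMm
  if (.ruleOn(cfg, "ETT_LOW") && dMm > 0 && low)
    return(list(category = "Borderline", fired = "ETT_LOW"))
  high <- if (inc) dMm > cfg@ettMaxMm else dMm >= cfg@ettMaxMm
  if (.ruleOn(cfg, "ETT_HIGH") && high)
    return(list(category = "Borderline", fired = "ETT_HIGH"))
  list(category = "Normal", fired = character(0))
}

#' Geometric category of a nasogastric tube
#'
#' The NGT tip should lie at least 10 cm beyond the gastro-esophageal
#' junction (four posterior ribs). Beyond it but short of 10 cm is
#' Borderline (a tip exactly at the junction counts as Borderline too: it has
#' entered the stomach inlet but advanced no further); above the junction is
#' Abnormal. A tube whose tip runs off the film with under 10 cm visible is
#' IncompletelyImaged.
#'
#' @param dBeyondMm arc length of the tube beyond the GE junction (mm, >= 0;
#'   `NA` when the junction landmark is absent)
#' @param aboveGej flag: tip cranial to the GE junction
#' @param incomplete flag from [isIncompletelyImaged()]
#' @param visibleLenMm visible line length (mm) from [visibleLineLengthMm()]
#' @param cfg a [RuleConfig-class]
#' @return list with `category` and `fired`
#' @export
classifyNgt <- function(dBeyondMm, aboveGej = FALSE, incomplete = FALSE,
                        visibleLenMm = Inf, cfg = RuleConfig()) {
  if (.ruleOn(cfg, "NGT_INCOMPLETE") && isTRUE(incomplete) &&
      visibleLenMm < cfg@ngtMinMm)
    return(list(category = "IncompletelyImaged", fired = "NGT_INCOMPLETE"))
  if (is.na(dBeyondMm) && !isTRUE(aboveGej))
    return(list(category = "Indeterminate", fired = character(0)))
  if (.ruleOn(cfg, "NGT_ABOVE_GEJ") && isTRUE(aboveGej))
    return(list(category = "Abnormal", fired = "NGT_ABOVE_GEJ"))
  if (is.na(dBeyondMm))
    return(list(category = "Indeterminate", fired = character(0)))
  if (.ruleOn(cfg, "NGT_SHORT") && dBeyondMm >= 0 && dBeyondMm < cfg@ngtMinMm)
    return(list(category = "Borderline", fired = "NGT_SHORT"))
  list(category = "Normal", fired = character(0))
}

#' Geometric category of a central venous catheter tip
#'
#' The CVC tip should lie in the SVC above the cavoatrial junction. Below the
#' junction but within the configured upper-right-atrium band is Borderline;
#' deeper is Abnormal. Swan-Ganz catheters are labeled Normal by convention
#' (their sheath end cannot be delineated). When an aortic-arch upper margin
#' is annotated, a tip above it (proximal to the SVC) is Borderline. The
#' vessel-wall angle criterion is not evaluated: it needs vessel anatomy that
#' tip coordinates cannot supply.
#'
#' @param dMm signed distance from tip to cavoatrial junction (mm, positive
#'   above), `NA` when the junction landmark is absent
#' @param swanGanz flag: Swan-Ganz catheter present
#' @param belowArch optional flag: tip below the upper aortic arch margin
#'   (`NA` when that level is not annotated; the clause is then skipped)
#' @param cfg a [RuleConfig-class]
#' @return list with `category` and `fired`
#' @export
classifyCvc <- function(dMm, swanGanz = FALSE, belowArch = NA,
                        cfg = RuleConfig()) {
  if (.ruleOn(cfg, "SWAN_GANZ_NORMAL") && isTRUE(swanGanz))
    return(list(category = "Normal", fired = "SWAN_GANZ_NORMAL"))
  if (is.na(dMm)) return(list(category = "Indeterminate", fired = character(0)))
  if (.ruleOn(cfg, "CVC_BELOW_RA_THIRD") && dMm < -cfg@raUpperThirdMm)
    return(list(category = "Abnormal", fired = "CVC_BELOW_RA_THIRD"))
  if (.ruleOn(cfg, "CVC_BELOW_CAJ") && dMm < 0)
    return(list(category = "Borderline", fired = "CVC_BELOW_CAJ"))
  if (.ruleOn(cfg, "CVC_ABOVE_ARCH") && identical(belowArch, FALSE))
    return(list(category = "Borderline", fired = "CVC_ABOVE_ARCH"))
  list(category = "Normal", fired = character(0))
}

#' Rule-based correction of classifier scores
#'
#' For each tube whose geometric category is strictly worse than the category
#' currently winning the classifier's scores (ordering Normal < Borderline <
#' Abnormal), the two implicated label scores are swapped, upgrading the
#' prediction while preserving the score set. Downgrades never fire: geometry
#' can only push a prediction toward a worse category, mirroring the clinical
#' upgrade reading of the criteria. Indeterminate and IncompletelyImaged
#' geometry leaves scores untouched, as does an argmax on a label without a
#' severity rank (NGT_IncompletelyImaged).
#'
#' @param scores a [ClassScores-class]
#' @param decisions named list with optional entries `ETT`, `NGT`, `CVC`; each
#'   a list with at least `category` (and optionally `fired`, `dVerticalMm`,
#'   `dEuclideanMm`) as returned by the `classify*` functions
#' @param cfg a [RuleConfig-class]
#' @return list with `adjustedScores` (a [ClassScores-class]) and `decisions`
#'   (named list of [RuleDecision-class], one per tube in `decisions`)
#' @examples
#' s <- setNames(rep(0.05, 11), RANZCR_LABELS)
#' s[c("ETT_Normal", "ETT_Borderline", "ETT_Abnormal")] <- c(0.8, 0.15, 0.05)
#' out <- applyRules(ClassScores(s), list(ETT = classifyEtt(20)))
#' scoreVector(out$adjustedScores)[1:3]   # Normal/Borderline swapped
#' @export
applyRules <- function(scores, decisions, cfg = RuleConfig()) {
  scores <- ClassScores(scores)
  s <- scoreVector(scores)
  out <- list()
  for (tube in names(decisions)) {
    dec <- decisions[[tube]]
    if (is.null(dec)) next
    if (!tube %in% names(TUBE_LABEL_GROUPS)) stop("unknown tube kind: ", tube)
    group <- TUBE_LABEL_GROUPS[[tube]]
    cat <- dec$category
    fired <- dec$fired %||% character(0)
    if (cat %in% names(.CATEGORY_RANK)) {
      gs <- s[group]
      argmax <- group[which.max(gs)]
      argmaxCat <- sub(paste0(tube, "_"), "", argmax)
      if (argmaxCat %in% names(.CATEGORY_RANK) &&
          .CATEGORY_RANK[[cat]] > .CATEGORY_RANK[[argmaxCat]]) {
        target <- paste0(tube, "_", cat)
        tmp <- s[[argmax]]
        s[[argmax]] <- s[[target]]
        s[[target]] <- tmp
      }
    }
    out[[tube]] <- list(category = cat, fired = fired,
                        dVerticalMm = dec$dVerticalMm %||% NA_real_,
                        dEuclideanMm = dec$dEuclideanMm %||% NA_real_)
  }
  adjusted <- ClassScores(s)
  decs <- lapply(names(out), function(tube) {
    group <- TUBE_LABEL_GROUPS[[tube]]
    new("RuleDecision",
      tubeKind = tube,
      geometricCategory = out[[tube]]$category,
      firedRules = out[[tube]]$fired,
      dVerticalMm = out[[tube]]$dVerticalMm,
      dEuclideanMm = out[[tube]]$dEuclideanMm,
      adjustedScores = adjusted,
      finalLabel = group[which.max(s[group])]
    )
  })
  names(decs) <- names(out)
  list(adjustedScores = adjusted, decisions = decs)
}

#' Run the full post-segmentation pipeline on one radiograph
#'
#' Extracts tube tips from the mask channels, measures their distances to the
#' reference landmarks, derives each tube's geometric category and applies the
#' rule-based score correction. Tubes whose channels are empty are skipped
#' (absent, not assessed); rules whose landmark is missing return
#' Indeterminate and leave scores unchanged.
#'
#' @param masks a [MaskChannelSet-class]
#' @param landmarks a [LandmarkSet-class]
#' @param scores a [ClassScores-class]
#' @param cfg a [RuleConfig-class]
#' @param swanGanz flag: Swan-Ganz catheter present; by default taken from the
#'   `SwanGanzPresent` score at threshold 0.5
#' @return as [applyRules()], plus `tips` (named list of detected tip points)
#' @export
classifyImage <- function(masks, landmarks, scores, cfg = RuleConfig(),
                          swanGanz = NULL) {
  stopifnot(is(masks, "MaskChannelSet"), is(landmarks, "LandmarkSet"))
  scores <- ClassScores(scores)
  meta <- masks@meta
  if (is.null(swanGanz))
    swanGanz <- scoreVector(scores)[["SwanGanzPresent"]] >= 0.5
  decisions <- list()
  tips <- list()

  measure <- function(tip, ref) {
    dv <- verticalSeparationMm(tip, ref, meta)
    de <- euclideanDistanceMm(tip, ref, meta)
    d <- if (cfg@distanceMode == "vertical") dv else sign(dv) * de
    list(dv = dv, de = de, d = d)
  }

  # ETT: tip channel vs carina
  ettComps <- findComponents(maskChannel(masks, "ett_tip"))
  if (nrow(ettComps)) {
    carina <- landmark(landmarks, "carina")
    det <- selectTip(ettComps, "ETT", reference = carina, meta = if (is.null(carina)) NULL else meta)
    tips$ETT <- det$tip
    if (is.null(carina)) {
      decisions$ETT <- list(category = "Indeterminate", fired = character(0))
    } else {
      t1Above <- if (length(landmarks@t1LevelY))
        det$tip[["y"]] <= landmarks@t1LevelY else NA
      m <- measure(det$tip, carina)
      cls <- classifyEtt(m$d, t1Above = t1Above, cfg = cfg)
      decisions$ETT <- c(cls, list(dVerticalMm = m$dv, dEuclideanMm = m$de))
    }
  }

  # CVC: tip channel vs cavoatrial junction (nearest tip when several lines)
  cvcComps <- findComponents(maskChannel(masks, "cvc_tip"))
  if (nrow(cvcComps) || isTRUE(swanGanz)) {
    caj <- landmark(landmarks, "cavoatrial_junction")
    det <- if (nrow(cvcComps))
      selectTip(cvcComps, "CVC", reference = caj, meta = if (is.null(caj)) NULL else meta)
    else NULL
    if (!is.null(det)) tips$CVC <- det$tip
    if (isTRUE(swanGanz)) {
      cls <- classifyCvc(NA_real_, swanGanz = TRUE, cfg = cfg)
      m <- if (!is.null(det) && !is.null(caj)) measure(det$tip, caj) else
        list(dv = NA_real_, de = NA_real_)
      decisions$CVC <- c(cls, list(dVerticalMm = m$dv, dEuclideanMm = m$de))
    } else if (is.null(caj)) {
      decisions$CVC <- list(category = "Indeterminate", fired = character(0))
    } else {
      belowArch <- if (length(landmarks@aorticArchUpperY))
        det$tip[["y"]] >= landmarks@aorticArchUpperY else NA
      m <- measure(det$tip, caj)
      cls <- classifyCvc(m$d, swanGanz = FALSE, belowArch = belowArch, cfg = cfg)
      decisions$CVC <- c(cls, list(dVerticalMm = m$dv, dEuclideanMm = m$de))
    }
  }

  # NGT: line channel only; tip recovered from the skeleton
  ngtMask <- maskChannel(masks, "ngt_line")
  if (any(ngtMask == 1L)) {
    carina <- landmark(landmarks, "carina")
    gej <- landmark(landmarks, "ge_junction")
    info <- ngtTipFromLine(ngtMask, meta, carina = carina, gej = gej)
    tips$NGT <- info$tip
    if (is.null(gej)) {
      decisions$NGT <- list(category = "Indeterminate", fired = character(0))
    } else {
      pseudoTip <- data.frame(touchesBorder = info$tipOnBorder)
      incomplete <- isIncompletelyImaged(ngtMask, pseudoTip)
      aboveGej <- info$tip[["y"]] < gej[[2]]
      dBeyond <- if (aboveGej) 0 else info$dBeyondMm
      cls <- classifyNgt(dBeyond, aboveGej = aboveGej, incomplete = incomplete,
                         visibleLenMm = info$visibleLenMm, cfg = cfg)
      dv <- verticalSeparationMm(info$tip, gej, meta)
      de <- euclideanDistanceMm(info$tip, gej, meta)
      decisions$NGT <- c(cls, list(dVerticalMm = dv, dEuclideanMm = de))
    }
  }

  res <- applyRules(scores, decisions, cfg)
  res$tips <- tips
  res
}
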