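# Evaluation harness: one-vs-rest AUCs with bootstrap percentile CIs,
# group-averaged AUCs, landmark MAE with paired tests, and subgroup
# stratification.

#' One-vs-rest ROC AUC (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted one half; computed from average ranks.
#'
#' @param labels binary vector (logical or 0/1)
#' @param scores numeric score vector of the same length
#' @return AUC in `[0, 1]`
#' @examples
#' aucOneVsRest(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))  # 0.75
#' @export
aucOneVsRest <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (anyNA(labels) || anyNA(scores)) stop("labels/scores contain NA")
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("undefined AUC: need at least one positive and one negative case")
  r <- rank(scores)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Bootstrap percentile confidence interval for a dataset statistic
#'
#' Resamples rows (images) with replacement and returns the 2.5/97.5
#' percentile bounds around the full-sample point estimate. Resamples on
#' which the statistic is undefined (error or NA) are redrawn, up to
#' `10 * nBoot` attempts in total; optional stratified resampling keeps the
#' composition of a grouping variable fixed so rare classes cannot vanish.
#'
#' @param data data.frame or matrix (resampled by row) or vector (by element)
#' @param statistic function of one resampled `data` returning a scalar
#' @param nBoot number of bootstrap iterations (default 1000)
#' @param seed optional integer seed; the same seed reproduces the interval
#' @param strata optional vector (length `NROW(data)`) to stratify resampling
#' @param conf confidence level (default 0.95)
#' @return named numeric `c(point, lo, hi)`
#' @export
bootstrapCi <- function(data, statistic, nBoot = 1000, seed = NULL,
                        strata = NULL, conf = 0.95) {
  stopifnot(nBoot >= 1)
  n <- NROW(data)
  take <- if (is.data.frame(data) || is.matrix(data))
    function(i) data[i, , drop = FALSE] else function(i) data[i]
  point <- statistic(data)  # undefined on the full data propagates as error
  if (!is.null(seed)) set.seed(seed)
  strataIdx <- if (!is.null(strata)) split(seq_len(n), strata)
  drawIdx <- function() {
    if (is.null(strataIdx)) sample.int(n, n, replace = TRUE)
    else unlist(lapply(strataIdx, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]), use.names = FALSE)
  }
  vals <- numeric(nBoot)
  attempts <- 0L
  b <- 1L
  while (b <= nBoot) {
    attempts <- attempts + 1L
    if (attempts > 10L * nBoot)
      stop("bootstrap exhausted: statistic undefined on too many resamples")
    v <- tryCatch(statistic(take(drawIdx())), error = function(e) NA_real_)
    if (is.na(v)) next
    vals[b] <- v
    b <- b + 1L
  }
  a <- (1 - conf) / 2
  q <- stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  c(point = point, lo = q[1], hi = q[2])
}

#' Average per-label AUCs within a tube group
#'
#' Unweighted arithmetic mean over the group's defined labels (labels whose
#' AUC is undefined are dropped from the mean, not imputed).
#'
#' @param aucs numeric vector of per-label AUCs, `NA` = undefined
#' @return the averaged AUC; error when no label is defined
#' @export
groupAverageAuc <- function(aucs) {
  ok <- !is.na(aucs)
  if (!any(ok)) stop("undefined group AUC: no defined per-label AUC")
  mean(aucs[ok])
}

#' Landmark mean absolute error in millimetres
#'
#' Per-image Euclidean distance between predicted and ground-truth landmark
#' coordinates, reported as mean and SD. Images missing either annotation are
#' excluded and counted.
#'
#' @param predicted,truth n x 2 matrices (columns x, y in pixels); rows with
#'   any NA are excluded pairwise
#' @param meta a single [ImageMeta-class] (shared spacing) or list of one per
#'   image
#' @param sdType `"population"` (divide by n; default, descriptive convention)
#'   or `"sample"` (divide by n - 1)
#' @return list with `mean`, `sd`, `n`, `nExcluded` and the per-image
#'   `distances` (mm)
#' @export
landmarkMaeMm <- function(predicted, truth, meta,
                          sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  if (!all(dim(predicted) == dim(truth)) || ncol(predicted) != 2L)
    stop("predicted and truth must be n x 2 matrices of equal size")
  n0 <- nrow(predicted)
  metas <- if (is(meta, "ImageMeta")) rep(list(meta), n0) else meta
  if (length(metas) != n0) stop("meta must be one ImageMeta or one per image")
  ok <- stats::complete.cases(predicted) & stats::complete.cases(truth)
  if (!any(ok)) stop("no complete landmark pairs to compare")
  d <- vapply(which(ok), function(i) {
    m <- metas[[i]]
    sqrt(((predicted[i, 1] - truth[i, 1]) * m@spacingCol)^2 +
         ((predicted[i, 2] - truth[i, 2]) * m@spacingRow)^2)
  }, numeric(1))
  mu <- mean(d)
  s <- if (sdType == "population") sqrt(mean((d - mu)^2)) else stats::sd(d)
  list(mean = mu, sd = s, n = sum(ok), nExcluded = n0 - sum(ok), distances = d)
}

#' Paired comparison of per-image landmark distances
#'
#' Two-sided paired t-test on the per-image difference `b - a` (so a negative
#' mean difference means condition `b` has smaller errors), with a
#' t-distribution confidence interval. Identical inputs are NaN-guarded to a
#' zero difference with p = 1.
#'
#' @param a,b numeric distance vectors over the same images
#' @param conf confidence level
#' @return list with `meanDiff`, `lo`, `hi`, `p`, `n`
#' @export
pairedDifferenceTest <- function(a, b, conf = 0.95) {
  if (length(a) != length(b)) stop("a and b must pair the same images")
  if (length(a) < 2L) stop("need at least two paired observations")
  d <- b - a
  if (all(d == d[1])) {
    if (d[1] == 0) return(list(meanDiff = 0, lo = 0, hi = 0, p = 1, n = length(a)))
    return(list(meanDiff = d[1], lo = d[1], hi = d[1], p = 0, n = length(a)))
  }
  tt <- stats::t.test(b, a, paired = TRUE, conf.level = conf)
  list(meanDiff = unname(tt$estimate), lo = tt$conf.int[1], hi = tt$conf.int[2],
       p = tt$p.value, n = length(a))
}

#' Statistical-significance convention for CI-based comparisons
#'
#' A comparison is flagged significant only when the p-value is below 0.05
#' AND the two 95% confidence intervals do not overlap.
#'
#' @param p p-value of the paired test
#' @param ci1,ci2 numeric `c(lo, hi)` intervals of the two compared estimates
#' @return logical
#' @export
significanceFlag <- function(p, ci1, ci2) {
  !is.na(p) && p < 0.05 && (ci1[2] < ci2[1] || ci2[2] < ci1[1])
}

.scoresMatrix <- function(scores) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    m <- as.matrix(scores)
    miss <- setdiff(RANZCR_LABELS, colnames(m))
    if (length(miss)) stop("score matrix missing label(s): ", paste(miss, collapse = ", "))
    return(m[, RANZCR_LABELS, drop = FALSE])
  }
  if (is.list(scores))
    return(do.call(rbind, lapply(scores, function(s) scoreVector(ClassScores(s)))))
  stop("scores must be a matrix/data.frame or a list of ClassScores")
}

.truthBinary <- function(truth, label) {
  if (label == "SwanGanzPresent") {
    keep <- rep(TRUE, nrow(truth))
    pos <- !is.na(truth$swanGanz) & truth$swanGanz
  } else {
    tube <- sub("_.*", "", label)
    cat <- sub("^[A-Z]+_", "", label)
    keep <- !is.na(truth[[tube]])
    pos <- keep & truth[[tube]] == cat
  }
  list(keep = keep, pos = pos)
}

#' Evaluate classifier scores against ground truth
#'
#' Computes the one-vs-rest AUC with a bootstrap 95% CI for each of the 11
#' labels, and the group-averaged AUC per tube kind with a CI obtained by
#' bootstrapping the averaged statistic itself (not by averaging the
#' per-label intervals). Images where a tube is absent are excluded from that
#' tube's labels. Resampling is stratified on the tube's ground-truth
#' category so no category vanishes from a resample; labels undefined on the
#' full data (single-class ground truth) are reported as undefined, never
#' dropped silently.
#'
#' @param truth data.frame with columns `ETT`, `NGT`, `CVC` (position category
#'   per image or `NA` when the tube is absent) and logical `swanGanz`
#' @param scores score matrix (rows = images, columns = [RANZCR_LABELS]) or
#'   list of [ClassScores-class]
#' @param nBoot bootstrap iterations (default 1000)
#' @param seed integer seed for the bootstrap
#' @return an `EvalReport` (S3 list) with `perLabel` and `perGroup`
#'   data.frames, plus `nBoot` and `seed`
#' @export
evaluateCohort <- function(truth, scores, nBoot = 1000, seed = 1L) {
  sm <- .scoresMatrix(scores)
  if (nrow(sm) != nrow(truth)) stop("truth and scores must cover the same images")
  perLabel <- data.frame(
    label = RANZCR_LABELS, n = NA_integer_, nPos = NA_integer_,
    auc = NA_real_, lo = NA_real_, hi = NA_real_,
    status = "undefined", stringsAsFactors = FALSE
  )
  for (j in seq_along(RANZCR_LABELS)) {
    lb <- RANZCR_LABELS[j]
    tb <- .truthBinary(truth, lb)
    y <- tb$pos[tb$keep]
    s <- sm[tb$keep, lb]
    perLabel$n[j] <- length(y); perLabel$nPos[j] <- sum(y)
    if (length(y) == 0L || sum(y) == 0L || sum(!y) == 0L) next
    df <- data.frame(y = y, s = s)
    ci <- bootstrapCi(df, function(d) aucOneVsRest(d$y, d$s),
                      nBoot = nBoot, seed = seed + j, strata = y)
    perLabel$auc[j] <- ci[["point"]]
    perLabel$lo[j] <- ci[["lo"]]; perLabel$hi[j] <- ci[["hi"]]
    perLabel$status[j] <- "ok"
  }
  groups <- names(TUBE_LABEL_GROUPS)
  perGroup <- data.frame(
    group = groups, nLabels = NA_integer_, auc = NA_real_,
    lo = NA_real_, hi = NA_real_, status = "undefined", stringsAsFactors = FALSE
  )
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    labs <- TUBE_LABEL_GROUPS[[g]]
    defined <- labs[perLabel$status[match(labs, perLabel$label)] == "ok"]
    perGroup$nLabels[gi] <- length(defined)
    if (!length(defined)) next
    keep <- !is.na(truth[[g]])
    df <- data.frame(cat = truth[[g]][keep], sm[keep, defined, drop = FALSE],
                     check.names = FALSE)
    stat <- function(d) {
      mean(vapply(defined, function(lb) {
        cat <- sub("^[A-Z]+_", "", lb)
        aucOneVsRest(d$cat == cat, d[[lb]])
      }, numeric(1)))
    }
    ci <- bootstrapCi(df, stat, nBoot = nBoot, seed = seed + 100L + gi,
                      strata = df$cat)
    perGroup$auc[gi] <- ci[["point"]]
    perGroup$lo[gi] <- ci[["lo"]]; perGroup$hi[gi] <- ci[["hi"]]
    perGroup$status[gi] <- "ok"
  }
  structure(
    list(perLabel = perLabel, perGroup = perGroup, nBoot = nBoot, seed = seed,
         nImages = nrow(truth)),
    class = "EvalReport"
  )
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport over %d images (%d bootstrap iterations, seed %d)\n",
              x$nImages, x$nBoot, x$seed))
  pl <- x$perLabel
  for (i in seq_len(nrow(pl))) {
    if (pl$status[i] == "ok")
      cat(sprintf("  %-24s AUC %.3f (%.3f - %.3f)  n=%d (%d pos)\n",
                  pl$label[i], pl$auc[i], pl$lo[i], pl$hi[i], pl$n[i], pl$nPos[i]))
    else
      cat(sprintf("  %-24s undefined (n=%d, %d pos)\n", pl$label[i], pl$n[i], pl$nPos[i]))
  }
  pg <- x$perGroup
  for (i in seq_len(nrow(pg))) {
    if (pg$status[i] == "ok")
      cat(sprintf("  %-24s AUC %.3f (%.3f - %.3f)  [group average]\n",
                  paste0(pg$group[i], " average"), pg$auc[i], pg$lo[i], pg$hi[i]))
    else
      cat(sprintf("  %-24s undefined\n", paste0(pg$group[i], " average")))
  }
  invisible(x)
}

#' Stratified evaluation report
#'
#' Recomputes the full AUC report independently within each level of a
#' subgroup flag (e.g. radiographs with vs without ECG leads). Strata in
#' which metrics are undefined report them as undefined rather than being
#' dropped.
#'
#' @param truth,scores,nBoot,seed as in [evaluateCohort()]
#' @param flag logical vector over images, or the name of a logical column of
#'   `truth`
#' @return named list of `EvalReport`s (`"TRUE"`/`"FALSE"` strata); an empty
#'   stratum yields `NULL` with a warning
#' @export
stratifiedReport <- function(truth, scores, flag, nBoot = 1000, seed = 1L) {
  if (is.character(flag) && length(flag) == 1L) flag <- truth[[flag]]
  if (anyNA(flag)) stop("subgroup flag must be present for every image")
  sm <- .scoresMatrix(scores)
  out <- list()
  for (lev in c(TRUE, FALSE)) {
    sel <- flag == lev
    if (!any(sel)) {
      warning("stratum ", lev, " is empty")
      out[[as.character(lev)]] <- NULL
      next
    }
    out[[as.character(lev)]] <- evaluateCohort(
      truth[sel, , drop = FALSE], sm[sel, , drop = FALSE],
      nBoot = nBoot, seed = seed)
  }
  out
}
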