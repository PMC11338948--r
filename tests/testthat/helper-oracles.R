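# Independent oracles and fixture builders shared across the suite. Each
# oracle is deliberately coded by a different route than the implementation
# it checks (stack-based flood fill vs run/union-find labelling; all-pairs
# counting vs rank-based AUC; literal clause-by-clause truth table vs the
# rule engine's guarded dispatch).

# 8-connected labelling by explicit stack-based flood fill
oracleFloodFill <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  stack <- integer(H * W)
  for (seedIdx in which(mask == 1L)) {
    if (lab[seedIdx] > 0L) next
    cur <- cur + 1L
    sp <- 1L
    stack[1L] <- seedIdx
    lab[seedIdx] <- cur
    while (sp > 0L) {
      p <- stack[sp]; sp <- sp - 1L
      r <- (p - 1L) %% H + 1L
      c <- (p - 1L) %/% H + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > H || cc < 1L || cc > W) next
        q <- (cc - 1L) * H + rr
        if (mask[q] == 1L && lab[q] == 0L) {
          lab[q] <- cur
          sp <- sp + 1L
          stack[sp] <- q
        }
      }
    }
  }
  lab
}

# component summary table from an oracle label matrix, sorted like
# findComponents (pixelCount desc, minY asc, minX asc)
oracleComponentStats <- function(lab) {
  ks <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ks)) {
    return(data.frame(pixelCount = numeric(0), centroidX = numeric(0),
                      centroidY = numeric(0), minX = numeric(0), minY = numeric(0),
                      maxX = numeric(0), maxY = numeric(0), touchesBorder = logical(0)))
  }
  rows <- lapply(ks, function(k) {
    rc <- which(lab == k, arr.ind = TRUE)
    x <- rc[, 2] - 1; y <- rc[, 1] - 1
    data.frame(
      pixelCount = nrow(rc), centroidX = mean(x), centroidY = mean(y),
      minX = min(x), minY = min(y), maxX = max(x), maxY = max(y),
      touchesBorder = min(x) == 0 || min(y) == 0 ||
        max(x) == ncol(lab) - 1 || max(y) == nrow(lab) - 1
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$pixelCount, df$minY, df$minX), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# AUC by brute-force enumeration of all positive/negative pairs
oracleAucAllPairs <- function(labels, scores) {
  labels <- as.logical(labels)
  sp <- scores[labels]; sn <- scores[!labels]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Literal clause-by-clause coding of the position criteria, written as a
# flat truth table (independent of the engine's guard/dispatch structure).
# Categories under the full rule set with inclusive band edges.
oracleEttCategory <- function(d, t1Above = NA,
                              lo = 35, hi = 70) {
  if (is.na(d)) return("Indeterminate")
  if (d <= 0) return("Abnormal")
  if (isTRUE(t1Above)) return("Abnormal")
  if (d < lo) return("Borderline")
  if (d > hi) return("Borderline")
  "Normal"
}

oracleNgtCategory <- function(dBeyond, aboveGej = FALSE, incomplete = FALSE,
                              visibleLen = Inf, minMm = 100) {
  if (isTRUE(incomplete) && visibleLen < minMm) return("IncompletelyImaged")
  if (isTRUE(aboveGej)) return("Abnormal")
  if (is.na(dBeyond)) return("Indeterminate")
  if (dBeyond < minMm) return("Borderline")
  "Normal"
}

oracleCvcCategory <- function(d, swanGanz = FALSE, belowArch = NA, band = 25) {
  if (isTRUE(swanGanz)) return("Normal")
  if (is.na(d)) return("Indeterminate")
  if (d < -band) return("Abnormal")
  if (d < 0) return("Borderline")
  if (identical(belowArch, FALSE)) return("Borderline")
  "Normal"
}

# random binary mask of the given size and density
randomMask <- function(h, w, density) {
  matrix(as.integer(stats::runif(h * w) < density), h, w)
}

# uniform ClassScores vector with selected overrides
scoresWith <- function(...) {
  s <- stats::setNames(rep(0.05, length(RANZCR_LABELS)), RANZCR_LABELS)
  ov <- c(...)
  s[names(ov)] <- ov
  ClassScores(s)
}

# binormal scores/labels with a known true AUC (logistic-squashed)
binormalSample <- function(n, prevalence, targetAuc) {
  mu <- sqrt(2) * stats::qnorm(targetAuc)
  y <- stats::runif(n) < prevalence
  s <- stats::plogis(stats::rnorm(n, mean = ifelse(y, mu, 0), sd = 1))
  list(y = y, s = s)
}

# minimal explicit-VR little-endian DICOM with a pixel spacing attribute
writeSyntheticDicom <- function(path, spacing = "0.168\\0.168",
                                tag = c(0x0028, 0x0030)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  wtag <- function(g, e, vr, val) {
    writeBin(as.integer(c(g, e)), con, size = 2, endian = "little")
    writeBin(charToRaw(vr), con)
    v <- charToRaw(val)
    if (length(v) %% 2) v <- c(v, charToRaw(" "))
    writeBin(as.integer(length(v)), con, size = 2, endian = "little")
    writeBin(v, con)
  }
  wtag(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  wtag(0x0008, 0x0060, "CS", "CR")
  wtag(tag[1], tag[2], "DS", spacing)
  invisible(path)
}
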