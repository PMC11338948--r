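# Connected-component analysis and skeleton measurements on binary mask
# channels. Masks are integer matrices [row, col] = [y + 1, x + 1]; all
# reported coordinates are 0-based image points c(x, y).
#
# Components use 8-connectivity throughout: rasterized catheters are thin and
# frequently diagonal, and 4-connectivity would fragment them.

.checkBinary <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask %in% c(0L, 1L))) stop("mask is not binary: values outside {0, 1}")
  invisible(TRUE)
}

# Row-run representation + union-find labelling (two-pass equivalent).
# Returns NULL for an empty mask, else list(stats = data.frame, runs = df with
# comp index into stats). stats rows are sorted: pixelCount desc, then
# (minY, minX) asc.
.componentRuns <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  rows <- list(); starts <- list(); ends <- list()
  k <- 0L
  for (r in seq_len(H)) {
    v <- mask[r, ] == 1L
    if (!any(v)) next
    rl <- rle(v)
    e <- cumsum(rl$lengths)
    s <- e - rl$lengths + 1L
    sel <- rl$values
    k <- k + 1L
    rows[[k]] <- rep.int(r, sum(sel)); starts[[k]] <- s[sel]; ends[[k]] <- e[sel]
  }
  if (k == 0L) return(NULL)
  rr <- unlist(rows); rs <- unlist(starts); re <- unlist(ends)
  n <- length(rr)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # union runs in adjacent rows that overlap or touch diagonally (8-conn)
  rowIdx <- split(seq_len(n), rr)
  rowKeys <- as.integer(names(rowIdx))
  for (j in seq_along(rowKeys)[-1]) {
    if (rowKeys[j] - rowKeys[j - 1L] != 1L) next
    above <- rowIdx[[j - 1L]]; cur <- rowIdx[[j]]
    for (b in cur) {
      for (a in above) {
        if (rs[a] <= re[b] + 1L && rs[b] <= re[a] + 1L) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- match(root, unique(root))
  len <- re - rs + 1L
  sumX <- (rs + re - 2L) * len / 2        # 0-based column sum per run
  sumY <- (rr - 1L) * len
  agg <- function(v, f) as.numeric(tapply(v, comp, f))
  cnt <- as.numeric(tapply(len, comp, sum))
  stats <- data.frame(
    pixelCount = cnt,
    centroidX = agg(sumX, sum) / cnt,
    centroidY = agg(sumY, sum) / cnt,
    minX = agg(rs - 1L, min), minY = agg(rr - 1L, min),
    maxX = agg(re - 1L, max), maxY = agg(rr - 1L, max)
  )
  stats$touchesBorder <- stats$minX == 0 | stats$minY == 0 |
    stats$maxX == W - 1 | stats$maxY == H - 1
  ord <- order(-stats$pixelCount, stats$minY, stats$minX)
  stats <- stats[ord, , drop = FALSE]
  rownames(stats) <- NULL
  remap <- match(comp, ord)
  list(stats = stats, runs = data.frame(row = rr, start = rs, end = re, comp = remap))
}

#' Find 8-connected components of a binary mask
#'
#' Labels the foreground of a binary mask with 8-connectivity and summarises
#' each component. Components are returned sorted by pixel count (largest
#' first), ties broken by the bounding box position (`minY`, then `minX`).
#'
#' @param mask binary integer matrix (`[row, col]`, values in `{0, 1}`)
#' @return a data.frame with one row per component and columns `pixelCount`,
#'   `centroidX`, `centroidY` (exact fractional, 0-based), `minX`, `minY`,
#'   `maxX`, `maxY` (bounding box, 0-based) and `touchesBorder` (TRUE iff the
#'   bounding box meets any image edge). Zero rows for an empty mask.
#' @examples
#' m <- matrix(0L, 30, 30); m[21:23, 11:13] <- 1L
#' findComponents(m)
#' @export
findComponents <- function(mask) {
  .checkBinary(mask)
  cr <- .componentRuns(mask)
  if (is.null(cr)) {
    return(data.frame(
      pixelCount = numeric(0), centroidX = numeric(0), centroidY = numeric(0),
      minX = numeric(0), minY = numeric(0), maxX = numeric(0), maxY = numeric(0),
      touchesBorder = logical(0)
    ))
  }
  cr$stats
}

# binary mask containing only component `which` (row index into findComponents
# order)
.componentMask <- function(mask, cr, which = 1L) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  rn <- cr$runs[cr$runs$comp == which, , drop = FALSE]
  for (i in seq_len(nrow(rn)))
    out[rn$row[i], rn$start[i]:rn$end[i]] <- 1L
  out
}

# component cropped to its padded bounding box, with the 0-based offset of
# the crop origin (skeleton work scales with the crop, not the image)
.cropComponent <- function(mask, cr, which = 1L, pad = 2L) {
  st <- cr$stats[which, ]
  r0 <- max(st$minY + 1L - pad, 1L); r1 <- min(st$maxY + 1L + pad, nrow(mask))
  c0 <- max(st$minX + 1L - pad, 1L); c1 <- min(st$maxX + 1L + pad, ncol(mask))
  sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
  rn <- cr$runs[cr$runs$comp == which, , drop = FALSE]
  for (i in seq_len(nrow(rn)))
    sub[rn$row[i] - r0 + 1L, (rn$start[i]:rn$end[i]) - c0 + 1L] <- 1L
  list(mask = sub, offX = c0 - 1L, offY = r0 - 1L)
}

#' Select the tip component for a tube
#'
#' Chooses one component from a tip channel. When a reference landmark is
#' given (e.g. the cavoatrial junction for CVC tips), the component whose
#' centroid is metrically closest to it wins -- with several catheters in the
#' field, the one closest to the reference anatomy is assessed. Without a
#' reference the largest component wins. Ties go to the larger component, then
#' to the component ordering of [findComponents()].
#'
#' @param components data.frame from [findComponents()] on the tip channel
#' @param tubeKind `"ETT"` or `"CVC"` (recorded in the result)
#' @param reference optional `c(x, y)` landmark point
#' @param meta an [ImageMeta-class]; required when `reference` is given
#' @return `NULL` when no component exists (tube not detected), else a list
#'   with elements `tubeKind`, `tip` (`c(x, y)`, the exact centroid),
#'   `component` (the chosen row) and `selectionRule` (`"largest"` or
#'   `"nearest_to_landmark"`)
#' @export
selectTip <- function(components, tubeKind = c("ETT", "CVC"),
                      reference = NULL, meta = NULL) {
  tubeKind <- match.arg(tubeKind)
  if (is.null(components) || nrow(components) == 0L) return(NULL)
  if (!is.null(reference)) {
    if (is.null(meta)) stop("meta is required to measure distances to the reference landmark")
    d <- vapply(seq_len(nrow(components)), function(i) {
      euclideanDistanceMm(
        c(components$centroidX[i], components$centroidY[i]), reference, meta)
    }, numeric(1))
    ord <- order(d, -components$pixelCount, seq_len(nrow(components)))
    i <- ord[1L]
    rule <- "nearest_to_landmark"
  } else {
    i <- 1L  # findComponents order: largest first, deterministic ties
    rule <- "largest"
  }
  list(
    tubeKind = tubeKind,
    tip = c(x = components$centroidX[i], y = components$centroidY[i]),
    component = components[i, , drop = FALSE],
    selectionRule = rule
  )
}

# --- skeletonization (Zhang-Suen thinning), vectorized over matrix shifts ----

.shiftN <- function(m) rbind(FALSE, m[-nrow(m), , drop = FALSE])
.shiftS <- function(m) rbind(m[-1, , drop = FALSE], FALSE)
.shiftW <- function(m) cbind(FALSE, m[, -ncol(m), drop = FALSE])
.shiftE <- function(m) cbind(m[, -1, drop = FALSE], FALSE)

#' Thin a binary mask to its skeleton
#'
#' Zhang-Suen iterative thinning; the result is an 8-connected, one-pixel-wide
#' curve approximating the medial axis. Used for visible-line length and for
#' recovering the nasogastric tube tip from its line channel.
#'
#' @param mask binary integer matrix
#' @return binary integer matrix of the same size
#' @export
skeletonize <- function(mask) {
  .checkBinary(mask)
  img <- mask == 1L
  if (!any(img)) return(matrix(0L, nrow(mask), ncol(mask)))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- .shiftN(img); p6 <- .shiftS(img)
      p8 <- .shiftW(img); p4 <- .shiftE(img)
      p3 <- .shiftN(p4); p5 <- .shiftS(p4)
      p7 <- .shiftS(p8); p9 <- .shiftN(p8)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1L) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- img & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        img <- img & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img <- .pruneCorners(img)
  matrix(as.integer(img), nrow(img))
}

# Remove staircase corners left by thinning: a skeleton pixel with exactly
# two neighbours that are themselves mutually 8-adjacent is a redundant
# corner (two axial steps standing in for one diagonal) and is deleted.
# Deletions within one sweep are kept mutually non-adjacent so the chain
# never disconnects; sweeps repeat until stable.
.pruneCorners <- function(img) {
  off <- cbind(
    dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
    dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
  )
  H <- nrow(img); W <- ncol(img)
  repeat {
    nb <- .shiftN(img) + .shiftS(img) + .shiftW(img) + .shiftE(img) +
      .shiftN(.shiftW(img)) + .shiftN(.shiftE(img)) +
      .shiftS(.shiftW(img)) + .shiftS(.shiftE(img))
    cand <- which(img & nb == 2)
    if (!length(cand)) break
    rc <- arrayInd(cand, dim(img))
    deletedRC <- NULL
    any_del <- FALSE
    for (i in seq_along(cand)) {
      r <- rc[i, 1]; c <- rc[i, 2]
      nbr <- off[img[cbind(pmin(pmax(r + off[, "dr"], 1), H),
                           pmin(pmax(c + off[, "dc"], 1), W))] &
                   r + off[, "dr"] >= 1 & r + off[, "dr"] <= H &
                   c + off[, "dc"] >= 1 & c + off[, "dc"] <= W, , drop = FALSE]
      if (nrow(nbr) != 2L) next
      if (max(abs(nbr[1, ] - nbr[2, ])) > 1L) next   # neighbours not adjacent
      if (!is.null(deletedRC) &&
          any(abs(deletedRC[, 1] - r) <= 1 & abs(deletedRC[, 2] - c) <= 1)) next
      img[r, c] <- FALSE
      deletedRC <- rbind(deletedRC, c(r, c))
      any_del <- TRUE
    }
    if (!any_del) break
  }
  img
}

# Edge list of a skeleton under full 8-connectivity.
# Arc lengths are measured as shortest paths through this graph, so the chain
# naturally takes a diagonal step where one exists instead of an axial detour.
# Returns list(nodes = data.frame(x, y, id), edges = data.frame(from, to, w)).
.skeletonGraph <- function(sk, meta) {
  s <- sk == 1L
  H <- nrow(s); W <- ncol(s)
  ids <- matrix(0L, H, W)
  idx <- which(s)
  ids[idx] <- seq_along(idx)
  rc <- arrayInd(idx, dim(s))
  nodes <- data.frame(x = rc[, 2] - 1, y = rc[, 1] - 1, id = seq_along(idx))
  wAx <- c(h = meta@spacingCol, v = meta@spacingRow)
  wD <- sqrt(meta@spacingRow^2 + meta@spacingCol^2)
  ed <- list(); k <- 0L
  addEdges <- function(from, to, w) {
    if (length(from)) {
      k <<- k + 1L
      ed[[k]] <<- data.frame(from = as.integer(from),
                             to = as.integer(to), w = unname(w))
    }
  }
  # horizontal: (r, c) - (r, c+1)
  selH <- s[, -W, drop = FALSE] & s[, -1, drop = FALSE]
  addEdges(ids[, -W, drop = FALSE][selH], ids[, -1, drop = FALSE][selH], wAx["h"])
  # vertical: (r, c) - (r+1, c)
  selV <- s[-H, , drop = FALSE] & s[-1, , drop = FALSE]
  addEdges(ids[-H, , drop = FALSE][selV], ids[-1, , drop = FALSE][selV], wAx["v"])
  # main diagonal: (r, c) - (r+1, c+1)
  selD <- s[-H, -W, drop = FALSE] & s[-1, -1, drop = FALSE]
  addEdges(ids[-H, -W, drop = FALSE][selD], ids[-1, -1, drop = FALSE][selD], wD)
  # anti-diagonal: (r, c+1) - (r+1, c)
  selA <- s[-H, -1, drop = FALSE] & s[-1, -W, drop = FALSE]
  addEdges(ids[-H, -1, drop = FALSE][selA], ids[-1, -W, drop = FALSE][selA], wD)
  edges <- if (k) do.call(rbind, ed) else data.frame(from = integer(0), to = integer(0), w = numeric(0))
  list(nodes = nodes, edges = edges)
}

# single-source shortest path distances along skeleton edges (Dijkstra on a
# sparse pixel graph; skeletons have at most a few thousand nodes)
.geodesic <- function(graph, source) {
  n <- nrow(graph$nodes)
  adj <- vector("list", n)
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- rbind(adj[[e$from[i]]], c(e$to[i], e$w[i]))
    adj[[e$to[i]]] <- rbind(adj[[e$to[i]]], c(e$from[i], e$w[i]))
  }
  dist <- rep(Inf, n)
  dist[source] <- 0
  done <- rep(FALSE, n)
  repeat {
    active <- which(!done & is.finite(dist))
    if (!length(active)) break
    u <- active[which.min(dist[active])]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      alt <- dist[u] + nb[, 2]
      upd <- alt < dist[nb[, 1]]
      dist[nb[upd, 1]] <- alt[upd]
    }
  }
  dist
}

#' Visible line length of a mask channel in millimetres
#'
#' Arc length along the skeleton of the largest connected component: the
#' end-to-end chain of adjacent skeleton pixels, axial steps contributing one
#' pixel spacing and diagonal steps `sqrt(spacingRow^2 + spacingCol^2)`
#' (computed as the geodesic diameter of the skeleton adjacency graph). Used
#' for the nasogastric-tube incompletely-imaged criterion (visible length
#' under 10 cm).
#'
#' @param lineMask binary integer matrix
#' @param meta an [ImageMeta-class]
#' @return length in mm; 0 for an empty mask
#' @export
visibleLineLengthMm <- function(lineMask, meta) {
  .checkBinary(lineMask)
  cr <- .componentRuns(lineMask)
  if (is.null(cr)) return(0)
  sub <- .cropComponent(lineMask, cr, 1L)
  g <- .skeletonGraph(skeletonize(sub$mask), meta)
  if (nrow(g$nodes) <= 1L || nrow(g$edges) == 0L) return(0)
  # geodesic diameter: two Dijkstra sweeps (exact on path-like skeletons)
  d1 <- .geodesic(g, 1L)
  a <- which.max(ifelse(is.finite(d1), d1, -1))
  d2 <- .geodesic(g, a)
  max(d2[is.finite(d2)])
}

#' Incomplete-imaging predicate for a line channel
#'
#' TRUE iff the largest line component touches the image border and no tip
#' component lies away from the border, i.e. the tube runs off the film
#' without its tip being captured in-field. Blank channels give FALSE: a tube
#' that is absent is not "incompletely imaged".
#'
#' @param lineMask binary line channel
#' @param tipComponents data.frame of tip components (from [findComponents()]
#'   on the tip channel, or a pseudo-component for the skeleton-derived NGT
#'   tip); may have zero rows or be `NULL`
#' @return logical flag
#' @export
isIncompletelyImaged <- function(lineMask, tipComponents = NULL) {
  .checkBinary(lineMask)
  comps <- findComponents(lineMask)
  if (nrow(comps) == 0L) return(FALSE)
  if (!comps$touchesBorder[1L]) return(FALSE)
  if (is.null(tipComponents) || nrow(tipComponents) == 0L) return(TRUE)
  !any(!tipComponents$touchesBorder)
}

#' Recover the nasogastric tube tip from the line channel
#'
#' The channel scheme has no NGT tip channel, so the tip is defined on the
#' line skeleton: when the carina is available, the skeleton point nearest the
#' carina anchors the proximal end and the tip is the skeleton point farthest
#' from it by arc length; without a carina the lowermost end of the skeleton
#' is used. The same skeleton yields the advancement beyond the
#' gastro-esophageal junction (arc length from the skeleton point nearest the
#' GE junction to the tip) and the visible line length.
#'
#' @param lineMask binary NGT line channel
#' @param meta an [ImageMeta-class]
#' @param carina optional `c(x, y)` carina point
#' @param gej optional `c(x, y)` gastro-esophageal junction point
#' @param borderMarginPx tolerance for calling the derived tip on-border;
#'   thinning erodes skeleton endpoints by up to the line half-thickness, so
#'   a tip within this many pixels of an edge counts as running off the film
#' @return `NULL` when the channel is empty, else a list with `tip` (`c(x, y)`),
#'   `tipOnBorder`, `dBeyondMm` (NA without `gej`), `visibleLenMm`,
#'   `usedFallback` (TRUE when the lowermost-endpoint fallback was used)
#' @export
ngtTipFromLine <- function(lineMask, meta, carina = NULL, gej = NULL,
                           borderMarginPx = 3) {
  .checkBinary(lineMask)
  cr <- .componentRuns(lineMask)
  if (is.null(cr)) return(NULL)
  sub <- .cropComponent(lineMask, cr, 1L)
  g <- .skeletonGraph(skeletonize(sub$mask), meta)
  g$nodes$x <- g$nodes$x + sub$offX
  g$nodes$y <- g$nodes$y + sub$offY
  n <- nrow(g$nodes)
  if (n == 0L) return(NULL)
  nearestNode <- function(p) {
    d2 <- ((g$nodes$x - p[[1]]) * meta@spacingCol)^2 +
          ((g$nodes$y - p[[2]]) * meta@spacingRow)^2
    which.min(d2)
  }
  usedFallback <- is.null(carina)
  if (!is.null(carina)) {
    anchor <- nearestNode(carina)
    dist <- .geodesic(g, anchor)
    tipId <- which.max(ifelse(is.finite(dist), dist, -1))
  } else {
    # gap-filling fallback: lowermost end of the skeleton diameter
    d1 <- .geodesic(g, 1L)
    a <- which.max(ifelse(is.finite(d1), d1, -1))
    d2 <- .geodesic(g, a)
    b <- which.max(ifelse(is.finite(d2), d2, -1))
    tipId <- if (g$nodes$y[a] > g$nodes$y[b] ||
                 (g$nodes$y[a] == g$nodes$y[b] && g$nodes$x[a] >= g$nodes$x[b])) a else b
  }
  tip <- c(x = g$nodes$x[tipId], y = g$nodes$y[tipId])
  dBeyond <- NA_real_
  if (!is.null(gej)) {
    gNode <- nearestNode(gej)
    dg <- .geodesic(g, gNode)
    dBeyond <- dg[tipId]
  }
  list(
    tip = tip,
    tipOnBorder = tip[["x"]] <= borderMarginPx || tip[["y"]] <= borderMarginPx ||
      tip[["x"]] >= meta@width - 1 - borderMarginPx ||
      tip[["y"]] >= meta@height - 1 - borderMarginPx,
    dBeyondMm = dBeyond,
    visibleLenMm = sum(g$edges$w),
    usedFallback = usedFallback
  )
}
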