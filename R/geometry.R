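# Metric distances between pixel points. Image convention: y grows downward,
# so "above" (cranial) means smaller y and a POSITIVE vertical separation.

.checkBound <- function(p, meta, what) {
  if (!is.numeric(p) || length(p) < 2L || anyNA(p[1:2]))
    stop(what, " must be a numeric c(x, y) point (image '", meta@imageId, "')")
  if (p[[1]] < 0 || p[[1]] >= meta@width || p[[2]] < 0 || p[[2]] >= meta@height)
    stop(what, " (", p[[1]], ", ", p[[2]], ") is outside image '",
         meta@imageId, "' (", meta@width, " x ", meta@height, ")")
  invisible(TRUE)
}

#' Signed cranio-caudal separation between a tube tip and a landmark
#'
#' Returns `(landmark_y - tip_y) * spacingRow` in millimetres. The sign
#' follows the clinical phrasing of the position criteria: positive means the
#' tip lies ABOVE (cranial to) the landmark, negative below.
#'
#' @param tip,landmark `c(x, y)` pixel points bound to `meta`
#' @param meta an [ImageMeta-class] supplying the row spacing
#' @return signed distance in mm
#' @examples
#' m <- ImageMeta(512, 512, 0.5)
#' verticalSeparationMm(c(100, 200), c(100, 270), m)  # +35: tip 70 px above
#' @export
verticalSeparationMm <- function(tip, landmark, meta) {
  stopifnot(is(meta, "ImageMeta"))
  .checkBound(tip, meta, "tip")
  .checkBound(landmark, meta, "landmark")
  (landmark[[2]] - tip[[2]]) * meta@spacingRow
}

#' Euclidean distance between two pixel points in millimetres
#'
#' Anisotropy-aware: horizontal displacement is scaled by the column spacing
#' and vertical displacement by the row spacing before taking the norm.
#'
#' @param a,b `c(x, y)` pixel points bound to `meta`
#' @param meta an [ImageMeta-class]
#' @return non-negative distance in mm
#' @examples
#' m <- ImageMeta(100, 100, 1)
#' euclideanDistanceMm(c(0, 0), c(3, 4), m)  # 5
#' @export
euclideanDistanceMm <- function(a, b, meta) {
  stopifnot(is(meta, "ImageMeta"))
  .checkBound(a, meta, "point a")
  .checkBound(b, meta, "point b")
  sqrt(((a[[1]] - b[[1]]) * meta@spacingCol)^2 +
       ((a[[2]] - b[[2]]) * meta@spacingRow)^2)
}
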