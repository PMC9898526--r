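# Polyline primitives and the triplet-based local measurement operators.

.segLengths <- function(p) {
  d <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  sqrt(d[, 1]^2 + d[, 2]^2)
}

.arcLength <- function(p) c(0, cumsum(.segLengths(p)))

## Linear interpolation along a polyline at arc-length positions s (vectorized).
.pointAt <- function(p, s) {
  cs <- .arcLength(p)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- pmin(i, nrow(p) - 1L)
  w <- (s - cs[i]) / (cs[i + 1L] - cs[i])
  p[i, , drop = FALSE] + w * (p[i + 1L, , drop = FALSE] - p[i, , drop = FALSE])
}

## Circumcircle through triplet a, b, c. Returns list(kappa = signed curvature,
## center). Sign convention: positive when the circumcenter lies on the +z
## (inward/basal) side of the chord a->c, so that deepening under positive
## tension corresponds to positive curvature. Collinear triplets give exactly 0.
.circumcircle <- function(a, b, c) {
  d1 <- b - a; d2 <- c - b; d3 <- c - a
  cross <- d1[1] * d2[2] - d1[2] * d2[1]
  if (cross == 0) return(list(kappa = 0, center = c(NA_real_, NA_real_)))
  den <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  sa <- sum(a^2); sb <- sum(b^2); sc <- sum(c^2)
  ux <- (sa * (b[2] - c[2]) + sb * (c[2] - a[2]) + sc * (a[2] - b[2])) / den
  uy <- (sa * (c[1] - b[1]) + sb * (a[1] - c[1]) + sc * (b[1] - a[1])) / den
  center <- c(ux, uy)
  k <- 2 * abs(cross) / sqrt(sum(d1^2) * sum(d2^2) * sum(d3^2))
  n <- .plusZNormal(d3)
  s <- sign(sum((center - b) * n))
  list(kappa = s * k, center = center)
}

## Unit normal to a tangent/chord vector, oriented toward +z (depth); for a
## vertical chord (no z component available) the +x normal is used.
.plusZNormal <- function(tangent) {
  n <- c(-tangent[2], tangent[1])
  n <- n / sqrt(sum(n^2))
  if (n[2] < 0 || (n[2] == 0 && n[1] < 0)) n <- -n
  n
}

## Triplet (anchor plus the two points half_span away along arc length).
## Returns NULL when out of support.
.triplet <- function(p, s, halfSpan) {
  L <- .arcLength(p)[nrow(p)]
  if (s - halfSpan < -1e-9 || s + halfSpan > L + 1e-9) return(NULL)
  list(lo = drop(.pointAt(p, s - halfSpan)),
       mid = drop(.pointAt(p, s)),
       hi = drop(.pointAt(p, s + halfSpan)))
}

#' Signed curvature of the circle through three points
#'
#' The triplet primitive underlying [localCurvature()]: curvature is the
#' inverse circumradius of the circle through the three points, signed
#' positive when the circumcenter lies on the +z (inward) side of the
#' chord `p1 -> p3`. A collinear triplet returns exactly 0. Exact (to
#' floating precision) whenever the three points lie on a circle.
#'
#' @param p1,p2,p3 numeric `c(x, z)` points (um).
#' @return Signed curvature (1/um).
#' @export
circumcircleCurvature <- function(p1, p2, p3) {
  .circumcircle(p1, p2, p3)$kappa
}

#' Resample a fold front to uniform arc-length spacing
#'
#' Points are placed on the input polyline at equally spaced arc-length
#' positions; the first and last input points are preserved exactly.
#'
#' @param front a [FoldFront-class].
#' @param nPoints number of output points (>= 3).
#' @return A resampled [FoldFront-class].
#' @export
resampleFront <- function(front, nPoints) {
  if (nPoints < 3) .configError("nPoints must be >= 3")
  p <- frontPoints(front)
  L <- .arcLength(p)[nrow(p)]
  if (L <= 0) .geometryError("degenerate zero-length polyline")
  q <- .pointAt(p, seq(0, L, length.out = nPoints))
  q[1, ] <- p[1, ]
  q[nPoints, ] <- p[nrow(p), ]
  FoldFront(q, time = frontTime(front), side = frontSide(front))
}

#' Local curvature by circumcircle fit on a triplet of points
#'
#' Fits a circle through the point at arc-length `position` and the two
#' points `halfSpan` away along arc length on either side; local curvature is
#' the inverse of the circumradius, signed positive when the osculating
#' center lies on the +z (inward) side. Collinear triplets return exactly 0.
#'
#' @param front a [FoldFront-class].
#' @param position arc-length position of the anchor (um from the first point).
#' @param halfSpan arc-length distance to the flanking points (um, default 22.5).
#' @return Signed curvature (1/um), or `NA` when the position is closer than
#'   `halfSpan` to either end of the front (out of support).
#' @export
localCurvature <- function(front, position, halfSpan = 22.5) {
  p <- frontPoints(front)
  vapply(position, function(s) {
    tri <- .triplet(p, s, halfSpan)
    if (is.null(tri)) return(NA_real_)
    .circumcircle(tri$lo, tri$mid, tri$hi)$kappa
  }, numeric(1))
}

## Intersections of the ray origin + u * dir with a polyline; returns sorted
## u values (all real u by default, or only u >= 0 when forwardOnly).
.rayPolylineIntersections <- function(origin, dir, p, forwardOnly = FALSE) {
  a <- p[-nrow(p), , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ez <- b[, 2] - a[, 2]
  den <- dir[1] * ez - dir[2] * ex
  rx <- a[, 1] - origin[1]; rz <- a[, 2] - origin[2]
  u <- (rx * ez - rz * ex) / den
  w <- (rx * dir[2] - rz * dir[1]) / den
  ok <- is.finite(u) & is.finite(w) & w >= -1e-9 & w <= 1 + 1e-9
  if (forwardOnly) ok <- ok & u >= -1e-9
  sort(u[ok])
}

#' Local normal deepening speed between consecutive fronts
#'
#' The local normal at `position` on the earlier front is the +z-oriented
#' perpendicular to the chord between the two triplet flanking points (same
#' triplet as [localCurvature()]). The speed is the signed distance from the
#' anchor to the intersection of this normal with the later (piecewise
#' linear) front, divided by the time difference; positive means deepening.
#'
#' @param frontT,frontT1 fronts at times t and t+1 (t1 > t).
#' @param position arc-length position of the anchor on `frontT` (um).
#' @param halfSpan triplet half-span (um, default 22.5).
#' @return Speed in um/h, or `NA` when the position is out of support or the
#'   normal misses the later front.
#' @export
normalSpeed <- function(frontT, frontT1, position, halfSpan = 22.5) {
  dt <- frontTime(frontT1) - frontTime(frontT)
  if (!is.finite(dt) || dt <= 0) .configError("frontT1 must be later than frontT")
  p0 <- frontPoints(frontT)
  p1 <- frontPoints(frontT1)
  vapply(position, function(s) {
    tri <- .triplet(p0, s, halfSpan)
    if (is.null(tri)) return(NA_real_)
    n <- .plusZNormal(tri$hi - tri$lo)
    u <- .rayPolylineIntersections(tri$mid, n, p1)
    if (!length(u)) return(NA_real_)
    u[which.min(abs(u))] / dt
  }, numeric(1))
}

#' Tissue thickness between apical and basal fronts
#'
#' Distance from each requested apical position along the apical local
#' normal to the basal polyline.
#'
#' @param apicalFront,basalFront [FoldFront-class] objects at the same time.
#' @param positions arc-length anchors on the apical front (um); defaults to
#'   interior positions every `halfSpan/2`.
#' @param halfSpan triplet half-span for the apical normal (um).
#' @return data.frame with `position` and `thickness` (um, `NA` where the
#'   normal misses the basal front).
#' @export
tissueThickness <- function(apicalFront, basalFront, positions = NULL,
                            halfSpan = 22.5) {
  p0 <- frontPoints(apicalFront)
  L <- .arcLength(p0)[nrow(p0)]
  if (is.null(positions))
    positions <- seq(halfSpan, L - halfSpan, by = halfSpan / 2)
  p1 <- frontPoints(basalFront)
  th <- vapply(positions, function(s) {
    tri <- .triplet(p0, s, halfSpan)
    if (is.null(tri)) return(NA_real_)
    n <- .plusZNormal(tri$hi - tri$lo)
    u <- .rayPolylineIntersections(tri$mid, n, p1)
    if (!length(u)) return(NA_real_)
    abs(u[which.min(abs(u))])
  }, numeric(1))
  data.frame(position = positions, thickness = th)
}
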