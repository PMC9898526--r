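# Image operators: apical surface detection, offset projection, basal fiber
# segmentation/orientation, curvature-binned intensity.
#
# Images are plain numeric matrices [x = ML, y = AP]; stacks are [x, y, z]
# arrays. EBImage supplies the morphology (background subtraction as
# grayscale opening with a disc element, standing in for the rolling-ball
# plugin), labeling and resizing; skeletonization is a Zhang-Suen thinning
# implemented here since no installed package provides one.

#' @importFrom EBImage opening makeBrush resize Image imageData
NULL

#' Rolling-ball style background subtraction
#'
#' Grayscale morphological opening with a disc structuring element of the
#' given radius, subtracted from the image.
#'
#' @param image numeric matrix.
#' @param radiusPx structuring-element radius in pixels (>= 1).
#' @return Background-subtracted matrix (nonnegative where the opening is
#'   a lower envelope).
#' @export
subtractBackground <- function(image, radiusPx) {
  if (radiusPx < 1) .configError("radiusPx must be >= 1")
  side <- 2L * as.integer(ceiling(radiusPx)) + 1L
  brush <- makeBrush(side, shape = "disc")
  ## EBImage grayscale morphology assumes [0, 1] data; normalize and restore
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image - image)
  bg <- imageData(opening(Image((image - lo) / (hi - lo)), brush)) * (hi - lo) + lo
  image - bg
}

## Zhang-Suen binary thinning. mask: logical matrix. Vectorized over the
## image via shifted copies; iterates to a fixed point.
.thin <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  core <- function(M, di, dj) M[(2L + di):(nr - 1L + di), (2L + dj):(nc - 1L + dj)]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- core(m, -1L, 0L); p3 <- core(m, -1L, 1L); p4 <- core(m, 0L, 1L)
      p5 <- core(m, 1L, 1L);  p6 <- core(m, 1L, 0L);  p7 <- core(m, 1L, -1L)
      p8 <- core(m, 0L, -1L); p9 <- core(m, -1L, -1L)
      p1 <- core(m, 0L, 0L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) + (p4 == 0L & p5 == 1L) +
           (p5 == 0L & p6 == 1L) + (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (pass == 1) {
        del <- p1 == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        del <- p1 == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(del)) {
        changed <- TRUE
        inner <- m[2:(nr - 1L), 2:(nc - 1L)]
        inner[del] <- 0L
        m[2:(nr - 1L), 2:(nc - 1L)] <- inner
      }
    }
    if (!changed) break
  }
  m[2:(nr - 1L), 2:(nc - 1L)] == 1L
}

## Crossing number: 0->1 transitions around the 8-neighborhood (circular
## order). 1 = line end, 2 = interior line pixel, >= 3 = junction. Raw
## neighbor counts misclassify staircase pixels of diagonal lines.
.crossingNumber <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  core <- function(di, dj) m[(2L + di):(nr - 1L + di), (2L + dj):(nc - 1L + dj)]
  p2 <- core(-1L, 0L); p3 <- core(-1L, 1L); p4 <- core(0L, 1L)
  p5 <- core(1L, 1L);  p6 <- core(1L, 0L);  p7 <- core(1L, -1L)
  p8 <- core(0L, -1L); p9 <- core(-1L, -1L)
  (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) + (p4 == 0L & p5 == 1L) +
    (p5 == 0L & p6 == 1L) + (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
    (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
}

## 8-connected component labels of a sparse logical matrix (BFS).
.label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(lab)
  cur <- 0L
  for (k in seq_len(nrow(idx))) {
    i0 <- idx[k, 1]; j0 <- idx[k, 2]
    if (lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), 1)
    lab[i0, j0] <- cur
    while (nrow(queue)) {
      nxt <- NULL
      for (q in seq_len(nrow(queue))) {
        i <- queue[q, 1]; j <- queue[q, 2]
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || jj < 1 || ii > nrow(mask) || jj > ncol(mask)) next
          if (mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            nxt <- rbind(nxt, c(ii, jj))
          }
        }
      }
      queue <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
    }
  }
  lab
}

## 8-neighbor counts of a logical matrix.
.neighborCount <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0L, nrow(mask), ncol(mask))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    s <- s + m[(2L + di):(nr - 1L + di), (2L + dj):(nc - 1L + dj)]
  }
  s
}

#' Segment fibers and measure their orientation
#'
#' Background-subtract (grayscale opening, radius `backgroundRadiusPx`),
#' threshold, skeletonize (Zhang-Suen), remove skeleton branch points
#' (vertices, >= 3 neighbors) so only linear portions remain, and turn each
#' remaining connected component into a fiber segment. Length is the
#' distance between the two skeleton endpoints; orientation is the endpoint
#' angle relative to the ML (x) axis folded into [0, 90]. Segments with
#' length <= `minLengthUm` are dropped.
#'
#' @param image numeric matrix (first index ML).
#' @param pixelSizeUm pixel size (um).
#' @param binarizeThreshold intensity threshold after background
#'   subtraction (operator-chosen; no default is presented as correct).
#' @param backgroundRadiusPx opening radius (px, default 3).
#' @param minLengthUm minimum fiber length (um, default 0.8).
#' @return data.frame with `x1`, `y1`, `x2`, `y2` (um), `length` (um),
#'   `orientation` (degrees in [0, 90]); empty when nothing survives.
#' @export
segmentFibers <- function(image, pixelSizeUm, binarizeThreshold,
                          backgroundRadiusPx = 3, minLengthUm = 0.8) {
  bs <- subtractBackground(image, backgroundRadiusPx)
  bw <- bs > binarizeThreshold
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), length = numeric(0),
                      orientation = numeric(0))
  if (!any(bw)) return(empty)
  sk <- .thin(bw)
  cn <- .crossingNumber(sk)
  vert <- sk & cn >= 3L
  if (any(vert)) {
    ## remove vertices together with their 8-neighborhood: the arm stubs
    ## around a removed junction stay diagonally connected otherwise
    sk[vert | .neighborCount(vert) > 0L] <- FALSE
  }
  if (!any(sk)) return(empty)
  lab <- .label8(sk)
  segs <- lapply(seq_len(max(lab)), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < 2) return(NULL)
    pts <- (idx - 0.5) * pixelSizeUm
    ## endpoints: the component is a linear path; take the farthest pair,
    ## seeded from the point farthest from the centroid
    ctr <- colMeans(pts)
    i1 <- which.max((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    d1 <- (pts[, 1] - pts[i1, 1])^2 + (pts[, 2] - pts[i1, 2])^2
    i2 <- which.max(d1)
    a <- pts[i1, ]; b <- pts[i2, ]
    len <- sqrt(sum((b - a)^2))
    data.frame(x1 = a[1], y1 = a[2], x2 = b[1], y2 = b[2], length = len,
               orientation = .foldAngle(atan2(b[2] - a[2], b[1] - a[1]) * 180 / pi))
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) return(empty)
  out <- out[out$length > minLengthUm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-weighted mean fiber orientation in an ROI
#'
#' Fibers whose midpoints fall inside the rectangle contribute their folded
#' orientation weighted by their length: `sum(length * orientation) /
#' sum(length)`.
#'
#' @param fibers data.frame from [segmentFibers()].
#' @param roi `c(xmin, xmax, ymin, ymax)` in um; `NULL` keeps all fibers.
#' @return Weighted mean orientation (degrees in [0, 90]); `NA` with a
#'   warning when no fiber midpoint lies in the ROI.
#' @export
weightedMeanOrientation <- function(fibers, roi = NULL) {
  if (!is.null(roi)) {
    mx <- (fibers$x1 + fibers$x2) / 2
    my <- (fibers$y1 + fibers$y2) / 2
    fibers <- fibers[mx >= roi[1] & mx <= roi[2] & my >= roi[3] & my <= roi[4], ]
  }
  if (!nrow(fibers)) {
    warning("no fibers in ROI")
    return(NA_real_)
  }
  sum(fibers$length * fibers$orientation) / sum(fibers$length)
}

## Running variance along z with a centered window (truncated at the ends).
.zVariance <- function(stack, window) {
  nz <- dim(stack)[3]
  hw <- (window - 1L) %/% 2L
  v <- array(NA_real_, dim = dim(stack))
  for (z in seq_len(nz)) {
    zz <- max(1L, z - hw):min(nz, z + hw)
    sl <- stack[, , zz, drop = FALSE]
    mu <- apply(sl, c(1, 2), mean)
    v[, , z] <- apply(sl, c(1, 2), function(x) mean(x^2)) - mu^2
  }
  v
}

## Block-mean downscale of a matrix by an integer factor (trailing partial
## blocks averaged over what they cover).
.blockMean <- function(m, f) {
  f <- as.integer(f)
  if (f <= 1L) return(m)
  ni <- ceiling(nrow(m) / f)
  nj <- ceiling(ncol(m) / f)
  out <- matrix(NA_real_, ni, nj)
  for (i in seq_len(ni)) {
    ri <- ((i - 1L) * f + 1L):min(i * f, nrow(m))
    for (j in seq_len(nj)) {
      cj <- ((j - 1L) * f + 1L):min(j * f, ncol(m))
      out[i, j] <- mean(m[ri, cj, drop = FALSE])
    }
  }
  out
}

#' Topographic map of the apical surface from a z-stack
#'
#' Per lateral pixel (after lateral downscaling) the along-z variance
#' profile is computed with a centered running window. Slices whose
#' variance exceeds `prominence` x (profile maximum) form high-variance
#' bands (runs of consecutive qualifying slices); the surface is the
#' variance-weighted centroid of the most apical band. The band centroid is
#' used rather than the raw variance argmax because a variance filter
#' applied across a thin bright band peaks on the band's two flanks, not
#' its center; the centroid of the enclosing high-variance run recovers the
#' center of a symmetric band exactly. The coarse map is then interpolated
#' back to the original lateral size.
#'
#' @param stack 3D array `[x, y, z]` (>= 3 slices).
#' @param downscale integer lateral downscale factor (default 10).
#' @param backgroundRadiusPx optional per-slice opening radius applied
#'   before the variance filter (`0` disables).
#' @param varWindow z-window of the variance filter (odd, default 9); it should cover the bulk of the surface band.
#' @param prominence band acceptance fraction of the profile maximum (default 0.3, low enough that the two flank peaks of one band stay in a single run).
#' @return Matrix of z positions (slice units, possibly fractional) at the
#'   original lateral size.
#' @export
apicalZMap <- function(stack, downscale = 10L, backgroundRadiusPx = 0L,
                       varWindow = 9L, prominence = 0.3) {
  if (dim(stack)[3] < 3) .configError("stack needs >= 3 slices")
  if (backgroundRadiusPx > 0)
    for (z in seq_len(dim(stack)[3]))
      stack[, , z] <- subtractBackground(stack[, , z], backgroundRadiusPx)
  if (downscale > 1L) {
    nz <- dim(stack)[3]
    small <- lapply(seq_len(nz), function(z) .blockMean(stack[, , z], downscale))
    stack2 <- array(0, dim = c(nrow(small[[1]]), ncol(small[[1]]), nz))
    for (z in seq_len(nz)) stack2[, , z] <- small[[z]]
  } else stack2 <- stack
  v <- .zVariance(stack2, varWindow)
  nz <- dim(v)[3]
  zmapSmall <- matrix(NA_real_, dim(v)[1], dim(v)[2])
  for (i in seq_len(dim(v)[1])) for (j in seq_len(dim(v)[2])) {
    prof <- v[i, j, ]
    top <- max(prof)
    if (top <= 0) .dataError("flat (zero-variance) stack: no surface detectable")
    high <- prof >= prominence * top
    ## most apical run of consecutive high-variance slices
    r <- rle(high)
    ends <- cumsum(r$lengths)
    k <- which(r$values)[1]
    zz <- (ends[k] - r$lengths[k] + 1L):ends[k]
    zmapSmall[i, j] <- sum(zz * prof[zz]) / sum(prof[zz])
  }
  if (downscale > 1L) {
    up <- imageData(resize(Image(zmapSmall), w = dim(stack)[1], h = dim(stack)[2]))
    up
  } else zmapSmall
}

#' Project a stack at an offset from the apical surface
#'
#' Per lateral pixel, reduces the slices in a window of `windowSlices`
#' centered at `round(zmap) + offsetSlices`; offsets outside the stack are
#' clamped to the first/last slice with a warning.
#'
#' @param stack 3D array `[x, y, z]`.
#' @param zmap matrix from [apicalZMap()] (same lateral size).
#' @param offsetSlices signed slice offset (0 = apical surface; positive =
#'   more basal).
#' @param reducer `"max"` or `"mean"`.
#' @param windowSlices window thickness (odd, default 1).
#' @return 2D matrix.
#' @export
projectOffset <- function(stack, zmap, offsetSlices = 0L,
                          reducer = c("max", "mean"), windowSlices = 1L) {
  reducer <- match.arg(reducer)
  nz <- dim(stack)[3]
  ctr <- round(zmap) + offsetSlices
  if (any(ctr < 1 | ctr > nz)) {
    warning("projection offset clamped to stack depth")
    ctr <- pmin(pmax(ctr, 1), nz)
  }
  hw <- (windowSlices - 1L) %/% 2L
  out <- matrix(NA_real_, nrow(zmap), ncol(zmap))
  red <- if (reducer == "max") max else mean
  for (i in seq_len(nrow(zmap))) for (j in seq_len(ncol(zmap))) {
    zz <- max(1L, ctr[i, j] - hw):min(nz, ctr[i, j] + hw)
    out[i, j] <- red(stack[i, j, zz])
  }
  out
}

#' Bin an intensity profile by matched local curvature
#'
#' Samples are grouped into curvature bins of fixed width (0.001 1/um);
#' each bin's mean intensity is then normalized by the unbinned all-sample
#' mean, so the count-weighted mean of the normalized bins is exactly 1.
#' Per-animal profiles computed this way can be averaged across animals.
#'
#' @param intensity intensity samples along the ML line.
#' @param curvature matched curvature samples (1/um, same length).
#' @param binWidth bin width (1/um, default 0.001).
#' @return data.frame with `bin_lo`, `bin_hi`, `norm_intensity`, `n_pixels`
#'   (empty bins dropped).
#' @export
intensityVsCurvature <- function(intensity, curvature, binWidth = 0.001) {
  if (length(intensity) != length(curvature)) .configError("length mismatch")
  ok <- is.finite(intensity) & is.finite(curvature)
  intensity <- intensity[ok]; curvature <- curvature[ok]
  if (!length(intensity)) .dataError("no finite samples")
  overall <- mean(intensity)
  b <- floor(curvature / binWidth)
  rows <- lapply(sort(unique(b)), function(bb) {
    sel <- b == bb
    data.frame(bin_lo = bb * binWidth, bin_hi = (bb + 1) * binWidth,
               norm_intensity = mean(intensity[sel]) / overall,
               n_pixels = sum(sel))
  })
  do.call(rbind, rows)
}
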