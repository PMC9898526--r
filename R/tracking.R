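# Material tracking of ML positions toward the convergence center, and the
# depth/thickness summaries built on it.

#' Point on a front at a given ML position
#'
#' First crossing of the vertical line x = `x0` by the polyline, by linear
#' interpolation between landmarks.
#'
#' @param front a [FoldFront-class].
#' @param x0 ML position(s) (um).
#' @return n x 2 matrix of points (`NA` rows where the front does not reach x0).
#' @export
frontPointAtX <- function(front, x0) {
  p <- frontPoints(front)
  out <- matrix(NA_real_, length(x0), 2, dimnames = list(NULL, c("x", "z")))
  for (j in seq_along(x0)) {
    dx <- p[, 1] - x0[j]
    if (any(dx == 0)) {
      out[j, ] <- p[which(dx == 0)[1], ]
      next
    }
    cross <- which(dx[-length(dx)] * dx[-1] < 0)
    if (!length(cross)) next
    i <- cross[1]
    w <- (x0[j] - p[i, 1]) / (p[i + 1, 1] - p[i, 1])
    out[j, ] <- p[i, ] + w * (p[i + 1, ] - p[i, ])
  }
  out
}

#' Track labeled ML positions toward a convergence center
#'
#' Each labeled Position_ML is assumed to move linearly in time toward a
#' fixed convergence center: its material trajectory is the intersection of
#' every front with the straight ray from the initial anchor point to the
#' center. Trajectories of distinct rays through one center never cross.
#'
#' @param series a [FrontSeries-class].
#' @param center numeric `c(x, z)`: the convergence center (um); x is the
#'   midline, z the final neck depth (an input, never a default - the adult
#'   depth is not derivable from the data).
#' @param anchorX initial ML positions of the tracked labels (um), read off
#'   the first front.
#' @param labels optional label vector (e.g. Position_ML in %).
#' @return data.frame with `label`, `time`, `x`, `z`, `s` (arc-length
#'   position on that front, um) and `truncated` (TRUE where the ray missed
#'   the front and the trajectory stops).
#' @export
trackTowardCenter <- function(series, center, anchorX, labels = anchorX) {
  fronts <- seriesFronts(series)
  q0 <- frontPointAtX(fronts[[1]], anchorX)
  rows <- vector("list", length(anchorX) * length(fronts))
  k <- 0L
  for (j in seq_along(anchorX)) {
    if (any(is.na(q0[j, ]))) next
    dir <- center - q0[j, ]
    nd <- sqrt(sum(dir^2))
    if (nd == 0) dir <- c(0, 1) else dir <- dir / nd
    for (f in fronts) {
      p <- frontPoints(f)
      u <- .rayPolylineIntersections(q0[j, ], dir, p, forwardOnly = TRUE)
      k <- k + 1L
      if (!length(u)) {
        rows[[k]] <- data.frame(label = labels[j], time = frontTime(f),
                                x = NA_real_, z = NA_real_, s = NA_real_,
                                truncated = TRUE)
        next
      }
      pt <- q0[j, ] + u[1] * dir
      ## arc-length coordinate of pt on this front
      cs <- .arcLength(p)
      d2 <- (p[, 1] - pt[1])^2 + (p[, 2] - pt[2])^2
      i <- which.min(d2)
      ## refine: project onto the two adjacent segments
      s <- cs[i]
      for (ii in c(i - 1L, i)) {
        if (ii < 1L || ii >= nrow(p)) next
        e <- p[ii + 1L, ] - p[ii, ]
        w <- sum((pt - p[ii, ]) * e) / sum(e^2)
        if (w >= -1e-9 && w <= 1 + 1e-9) s <- cs[ii] + w * sqrt(sum(e^2))
      }
      rows[[k]] <- data.frame(label = labels[j], time = frontTime(f),
                              x = pt[1], z = pt[2], s = s, truncated = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Neck depth over time
#'
#' Depth of each tracked Position_ML is the distance from its position on
#' the reference front (closest frame to `referenceTime`) to its current
#' position along the convergence ray; depths are then averaged over the
#' requested ML label range.
#'
#' @param series a [FrontSeries-class].
#' @param center convergence center `c(x, z)` (um).
#' @param anchorX tracked initial ML positions (um).
#' @param labels label values used for range selection (default `anchorX`).
#' @param referenceTime reference developmental time (hAPF, default 16).
#' @param labelRange labels kept for the average (default c(-250, 250),
#'   Position_ML %, when labels are percent).
#' @return data.frame with `time` and `depth` (um, 0 at the reference time).
#' @export
neckDepth <- function(series, center, anchorX, labels = anchorX,
                      referenceTime = 16, labelRange = c(-250, 250)) {
  tt <- seriesTimes(series)
  if (min(abs(tt - referenceTime)) > 1e-6 + max(diff(tt)))
    .configError("no front at or near the reference time")
  iRef <- which.min(abs(tt - referenceTime))
  traj <- trackTowardCenter(series, center, anchorX, labels)
  keep <- traj$label >= labelRange[1] & traj$label <= labelRange[2] & !traj$truncated
  traj <- traj[keep, , drop = FALSE]
  ref <- traj[abs(traj$time - tt[iRef]) < 1e-9, c("label", "x", "z")]
  names(ref) <- c("label", "x0", "z0")
  m <- merge(traj, ref, by = "label")
  m$d <- sqrt((m$x - m$x0)^2 + (m$z - m$z0)^2)
  agg <- aggregate(d ~ time, data = m, FUN = mean)
  data.frame(time = agg$time, depth = agg$d)
}
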