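# Forward simulation of the curvature-tension flow v_n = kappa * T(t) / mu.

#' Flow integrator configuration
#'
#' Explicit Euler stepping with a CFL-style step bound and optional per-step
#' uniform arc-length resampling (which prevents node clustering where the
#' flow compresses the curve).
#'
#' @param dtMax maximum step (h).
#' @param cflFraction step bound as a fraction of (shortest segment) /
#'   (largest normal speed); must be in (0, 1).
#' @param boundary `"fixed_endpoints"` (pinned tissue edges, default) or
#'   `"closed"` (periodic).
#' @param resampleEveryStep logical.
#' @param nPoints number of nodes carried by the integrator.
#' @return A list of class `flow_config`.
#' @export
flowConfig <- function(dtMax = 0.05, cflFraction = 0.2,
                       boundary = c("fixed_endpoints", "closed"),
                       resampleEveryStep = TRUE, nPoints = 181L) {
  if (cflFraction <= 0 || cflFraction >= 1)
    .configError("cflFraction must be in (0, 1)")
  if (dtMax <= 0) .configError("dtMax must be > 0")
  structure(list(dtMax = dtMax, cflFraction = cflFraction,
                 boundary = match.arg(boundary),
                 resampleEveryStep = resampleEveryStep,
                 nPoints = as.integer(nPoints)),
            class = "flow_config")
}

## Discrete curvature vectors from neighbor triplets (vectorized over nodes).
## kvec points toward the local circumcenter with magnitude |kappa|; this is
## orientation-independent, so the same update works for open and closed
## curves. Collinear triplets contribute a zero vector.
.curvatureVectors <- function(p, closed) {
  n <- nrow(p)
  if (closed) {
    a <- p[c(n, 1:(n - 1)), , drop = FALSE]
    b <- p
    cc <- p[c(2:n, 1), , drop = FALSE]
  } else {
    a <- p[1:(n - 2), , drop = FALSE]
    b <- p[2:(n - 1), , drop = FALSE]
    cc <- p[3:n, , drop = FALSE]
  }
  d1 <- b - a; d2 <- cc - b
  cross <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  den <- 2 * (a[, 1] * (b[, 2] - cc[, 2]) + b[, 1] * (cc[, 2] - a[, 2]) +
              cc[, 1] * (a[, 2] - b[, 2]))
  sa <- a[, 1]^2 + a[, 2]^2; sb <- b[, 1]^2 + b[, 2]^2; sc <- cc[, 1]^2 + cc[, 2]^2
  ux <- (sa * (b[, 2] - cc[, 2]) + sb * (cc[, 2] - a[, 2]) + sc * (a[, 2] - b[, 2])) / den
  uy <- (sa * (cc[, 1] - b[, 1]) + sb * (a[, 1] - cc[, 1]) + sc * (b[, 1] - a[, 1])) / den
  dx <- ux - b[, 1]; dy <- uy - b[, 2]
  r2 <- dx^2 + dy^2
  kv <- cbind(dx / r2, dy / r2)
  kv[cross == 0 | !is.finite(r2) | r2 == 0, ] <- 0
  kv
}

.resampleClosed <- function(p, n) {
  q <- rbind(p, p[1, ])
  L <- .arcLength(q)[nrow(q)]
  .pointAt(q, seq(0, L, length.out = n + 1))[seq_len(n), , drop = FALSE]
}

#' Simulate a fold front under the curvature-tension flow
#'
#' Integrates `v_n = kappa * T(t) / mu`: each node moves along the local
#' curvature vector (toward the osculating center) at speed `|kappa| T / mu`.
#' Explicit Euler with step `dt = min(dtMax, cflFraction * min_segment /
#' max_speed, cflFraction * min_segment^2 * mu / (2 T))` - the last bound
#' being the parabolic stability limit of this diffusive flow - clipped so
#' output frames are hit exactly. With
#' `fixed_endpoints` the two end nodes never move; with `closed` the node
#' ring is periodic.
#'
#' @param front0 initial [FoldFront-class]. For `boundary = "closed"` the
#'   points are interpreted as a ring (no repeated closing point).
#' @param schedule a [TensionSchedule-class].
#' @param mu dissipative prefactor (> 0, tension units x h / um).
#' @param tStart,tEnd simulated time range (hAPF).
#' @param config a [flowConfig()].
#' @param frameTimes output times; defaults to `seq(tStart, tEnd, length.out = 25)`.
#' @return A [FrontSeries-class] with one front per frame time.
#' @export
simulateFlow <- function(front0, schedule, mu, tStart, tEnd,
                         config = flowConfig(), frameTimes = NULL) {
  if (mu <= 0) .configError("mu must be > 0")
  if (tEnd <= tStart) .configError("tEnd must exceed tStart")
  if (is.null(frameTimes)) frameTimes <- seq(tStart, tEnd, length.out = 25)
  frameTimes <- sort(unique(c(tStart, frameTimes)))
  closed <- config$boundary == "closed"
  p <- frontPoints(front0)
  p <- if (closed) .resampleClosed(p, config$nPoints)
       else frontPoints(resampleFront(front0, config$nPoints))
  out <- vector("list", length(frameTimes))
  t <- tStart
  iOut <- 1L
  emit <- function(pts, tm) {
    FoldFront(if (closed) rbind(pts, pts[1, ]) else pts,
              time = tm, side = frontSide(front0))
  }
  if (abs(frameTimes[1] - t) < 1e-12) { out[[1]] <- emit(p, t); iOut <- 2L }
  maxSteps <- 1e6
  step <- 0L
  while (iOut <= length(frameTimes)) {
    step <- step + 1L
    if (step > maxSteps)
      .simulationError(sprintf(
        "integrator stalled before frame t = %g (step bound collapsed)", frameTimes[iOut]))
    kv <- .curvatureVectors(p, closed)
    Tt <- tensionAt(schedule, t)
    v <- (Tt / mu) * kv
    if (!closed) v <- rbind(0, v, 0)   # pinned endpoints
    vmax <- sqrt(max(rowSums(v^2)))
    minSeg <- min(.segLengths(if (closed) rbind(p, p[1, ]) else p))
    dt <- config$dtMax
    if (vmax > 0) dt <- min(dt, config$cflFraction * minSeg / vmax)
    ## parabolic stability: the flow linearizes to diffusion with D = T/mu,
    ## so explicit stepping also needs dt <= cfl * dx^2 / (2 D)
    if (Tt > 0) dt <- min(dt, config$cflFraction * minSeg^2 * mu / (2 * Tt))
    if (dt < 1e-10)
      .simulationError(sprintf(
        "stability bound forced dt < 1e-10 h before frame t = %g", frameTimes[iOut]))
    hit <- FALSE
    if (t + dt >= frameTimes[iOut] - 1e-12) { dt <- frameTimes[iOut] - t; hit <- TRUE }
    p <- p + v * dt
    t <- if (hit) frameTimes[iOut] else t + dt
    if (config$resampleEveryStep && vmax > 0) {
      p <- if (closed) .resampleClosed(p, nrow(p))
           else frontPoints(resampleFront(FoldFront(p), nrow(p)))
    }
    if (hit) { out[[iOut]] <- emit(p, t); iOut <- iOut + 1L }
  }
  FrontSeries(out, animalId = "simulated")
}

#' Curvature homogeneity (coefficient of variation) over time
#'
#' For each front, signed curvature is sampled at interior arc-length
#' positions (triplet half-span inside both ends) and summarized as
#' CV = sd(kappa) / mean(kappa). Under the curvature-tension flow more
#' curved regions deepen faster, so the CV of an initially heterogeneous
#' convex front decreases while its mean curvature grows.
#'
#' @param series a [FrontSeries-class].
#' @param halfSpan triplet half-span (um).
#' @param spacing arc-length sampling step (um, default `halfSpan / 4`).
#' @param margin arc length excluded at both ends of each front (um,
#'   default 225, never below `halfSpan`): on simulated strips this skips
#'   the boundary layers induced by the pinned endpoints (which spread
#'   about two diffusion lengths `sqrt(2 (T/mu) t)` over a run), and on
#'   tracked data the outermost positions are the least reliably sampled.
#' @param center,anchorX optional: when both are given, curvature is
#'   sampled at the material positions tracked toward the convergence
#'   `center` from initial ML positions `anchorX` (the same convention the
#'   measurement pipeline uses), instead of at fixed arc-length positions.
#'   Material sampling avoids the apparent early curvature loss of a fixed
#'   arc-length window, through whose edges curvature advects.
#' @return data.frame with `time`, `mean_kappa`, `cv` (`NA` when mean
#'   curvature is not positive).
#' @export
homogeneityCV <- function(series, halfSpan = 22.5, spacing = halfSpan / 4,
                          margin = 225, center = NULL, anchorX = NULL) {
  margin <- max(margin, halfSpan)
  fronts <- seriesFronts(series)
  if (!is.null(center) && !is.null(anchorX)) {
    traj <- trackTowardCenter(series, center, anchorX)
    rows <- lapply(fronts, function(f) {
      tj <- traj[abs(traj$time - frontTime(f)) < 1e-9 & !traj$truncated, ]
      k <- localCurvature(f, tj$s, halfSpan)
      k <- k[!is.na(k)]
      if (length(k) < 3) .geometryError("fewer than 3 tracked curvature samples")
      mk <- mean(k)
      data.frame(time = frontTime(f), mean_kappa = mk,
                 cv = if (mk > 0) sd(k) / mk else NA_real_)
    })
    return(do.call(rbind, rows))
  }
  ## fixed number of relative positions so the summary varies smoothly as
  ## the front shortens (no samples popping in and out at the window edge)
  L1 <- .arcLength(frontPoints(fronts[[1]]))[nrow(frontPoints(fronts[[1]]))]
  nS <- max(3L, floor((L1 - 2 * margin) / spacing) + 1L)
  rows <- lapply(fronts, function(f) {
    p <- frontPoints(f)
    L <- .arcLength(p)[nrow(p)]
    s <- seq(margin, L - margin, length.out = nS)
    if (length(s) < 3) .geometryError("front too short for >= 3 interior samples")
    k <- localCurvature(f, s, halfSpan)
    mk <- mean(k)
    data.frame(time = frontTime(f), mean_kappa = mk,
               cv = if (mk > 0) sd(k) / mk else NA_real_)
  })
  do.call(rbind, rows)
}
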