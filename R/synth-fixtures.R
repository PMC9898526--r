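# Synthetic fixtures: recoil traces, fiber images, z-stacks.

#' Synthetic ablation recoil trace
#'
#' Viscoelastic recoil: displacement `d(t) = v0 * tau * (1 - exp(-t/tau))`
#' plus optional Gaussian noise, sampled every `dt`. The initial slope is
#' `v0`; `d(0) = 0` when noise is 0.
#'
#' @param v0 initial recoil velocity (um/s, >= 0).
#' @param tau relaxation time (s, > 0).
#' @param duration trace length (s).
#' @param dt sampling interval (s, > 0).
#' @param noiseSd displacement noise sd (um).
#' @param seed integer seed (only affects the noise).
#' @return data.frame with `time` (s) and `displacement` (um).
#' @export
synthRecoilTrace <- function(v0, tau, duration = 30, dt = 1, noiseSd = 0,
                             seed = 1L) {
  if (v0 < 0 || tau <= 0) .configError("need v0 >= 0 and tau > 0")
  if (dt <= 0) .configError("dt must be > 0")
  t <- seq(0, duration, by = dt)
  d <- v0 * tau * (1 - exp(-t / tau))
  if (noiseSd > 0) {
    set.seed(seed)
    d <- d + rnorm(length(t), 0, noiseSd)
  }
  data.frame(time = t, displacement = d)
}

## Fold an angle (degrees) into [0, 90] relative to the ML axis.
.foldAngle <- function(thetaDeg) {
  m <- thetaDeg %% 180
  pmin(m, 180 - m)
}

#' Synthetic fiber image with ground truth
#'
#' Renders one bright straight bar per fiber spec on a uniform background.
#' Pixel centers within `width/2` of the bar's center segment get the bar
#' intensity. The truth table records the 0-90 folded orientation
#' (`min(theta mod 180, 180 - theta mod 180)`) and the endpoint length.
#' Image axes: first index is ML (x), second is AP (y).
#'
#' @param fiberSpecs data.frame with columns `cx`, `cy` (center, um),
#'   `angle` (deg in [0, 180)), `length`, `width` (um), `intensity`.
#' @param imageSize `c(nx, ny)` pixels.
#' @param pixelSize um per pixel (> 0).
#' @param background background level.
#' @param noiseSd Gaussian pixel noise sd.
#' @param seed integer seed.
#' @return list with `image` (matrix) and `truth` (data.frame `cx`, `cy`,
#'   `orientation` in [0, 90], `length`).
#' @export
synthFiberImage <- function(fiberSpecs, imageSize = c(128L, 128L),
                            pixelSize = 0.161, background = 10,
                            noiseSd = 0, seed = 1L) {
  if (pixelSize <= 0) .configError("pixelSize must be > 0")
  img <- matrix(background, imageSize[1], imageSize[2])
  xs <- (seq_len(imageSize[1]) - 0.5) * pixelSize
  ys <- (seq_len(imageSize[2]) - 0.5) * pixelSize
  n <- if (is.null(fiberSpecs)) 0L else nrow(fiberSpecs)
  truth <- data.frame(cx = numeric(0), cy = numeric(0),
                      orientation = numeric(0), length = numeric(0))
  for (i in seq_len(n)) {
    f <- fiberSpecs[i, ]
    if (f$angle < 0 || f$angle >= 180) .configError("angle must be in [0, 180)")
    th <- f$angle * pi / 180
    u <- c(cos(th), sin(th))
    a <- c(f$cx, f$cy) - u * f$length / 2
    b <- c(f$cx, f$cy) + u * f$length / 2
    if (min(a[1], b[1]) < 0 || max(a[1], b[1]) > imageSize[1] * pixelSize ||
        min(a[2], b[2]) < 0 || max(a[2], b[2]) > imageSize[2] * pixelSize)
      .configError(sprintf("fiber %d extends outside the image", i))
    X <- matrix(xs, imageSize[1], imageSize[2])
    Y <- matrix(ys, imageSize[1], imageSize[2], byrow = TRUE)
    ## distance from pixel centers to segment a-b
    apx <- X - a[1]; apy <- Y - a[2]
    ab <- b - a; L2 <- sum(ab^2)
    tproj <- pmin(pmax((apx * ab[1] + apy * ab[2]) / L2, 0), 1)
    dx <- apx - tproj * ab[1]; dy <- apy - tproj * ab[2]
    hit <- (dx^2 + dy^2) <= (f$width / 2)^2
    img[hit] <- f$intensity
    truth <- rbind(truth, data.frame(cx = f$cx, cy = f$cy,
                                     orientation = .foldAngle(f$angle),
                                     length = f$length))
  }
  if (noiseSd > 0) {
    set.seed(seed)
    img <- img + matrix(rnorm(length(img), 0, noiseSd), nrow(img))
  }
  list(image = img, truth = truth)
}

#' Synthetic z-stack with a known surface
#'
#' Each lateral pixel's z-profile is a Gaussian bump of amplitude
#' `signalAmplitude` and width `signalSdSlices` centered at that pixel's
#' `heightMap` value, plus optional Gaussian noise. The generator never
#' gates on quality: arbitrarily noisy stacks are valid outputs.
#'
#' @param heightMap matrix of surface z positions (slice units, within
#'   `[1, nSlices]`).
#' @param nSlices number of z slices.
#' @param signalAmplitude bump amplitude.
#' @param signalSdSlices bump sd (slices).
#' @param noiseSd additive noise sd.
#' @param seed integer seed.
#' @return 3D array `[x, y, z]`.
#' @export
synthZStack <- function(heightMap, nSlices = 40L, signalAmplitude = 100,
                        signalSdSlices = 1.5, noiseSd = 0, seed = 1L) {
  if (any(heightMap < 1 | heightMap > nSlices))
    .configError("heightMap values must lie within [1, nSlices]")
  nx <- nrow(heightMap); ny <- ncol(heightMap)
  stack <- array(0, dim = c(nx, ny, nSlices))
  for (z in seq_len(nSlices))
    stack[, , z] <- signalAmplitude * exp(-0.5 * ((z - heightMap) / signalSdSlices)^2)
  if (noiseSd > 0) {
    set.seed(seed)
    stack <- stack + array(rnorm(length(stack), 0, noiseSd), dim = dim(stack))
  }
  stack
}
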