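# Synthetic fold-front ensembles with known mu and tension schedule.

#' Construct an initial fold-front geometry
#'
#' All geometries are arc-length parameterized (uniform spacing) and
#' oriented so the curve is concave toward +z (osculating centers at +z,
#' positive curvature): the medial apex sits at (0, 0) and the flanks run
#' deeper laterally, matching a transverse section of the neck region.
#'
#' * `uniform_arc`: circular arc of radius `arcRadius`, centered on the apex.
#' * `flattened_medial`: the medial segment `|x| < flatHalfWidth` is a
#'   straight horizontal line (zero curvature, coverslip contact)
#'   tangentially joined to circular flanks of radius `arcRadius`.
#' * `flattened_lateral`: uniform arc whose outer left flank, beyond arc
#'   length `span/2 - 2*flatHalfWidth` from the apex, is replaced by its
#'   straight tangent continuation (flattened length `2*flatHalfWidth`).
#'
#' @param geometry one of the three geometry names.
#' @param arcRadius radius of the curved portions (um, > 0).
#' @param flatHalfWidth half-width of the flattened portion (um, >= 0).
#' @param span total arc length of the front (um); for `uniform_arc` must
#'   not exceed `pi * arcRadius`.
#' @param nPoints number of sampled points (>= 5).
#' @return A [FoldFront-class] with uniform arc-length spacing.
#' @export
makeInitialFront <- function(geometry = c("uniform_arc", "flattened_medial",
                                          "flattened_lateral"),
                             arcRadius = 300, flatHalfWidth = 100,
                             span = 900, nPoints = 181L) {
  if (length(geometry) == 1 && !geometry %in%
      c("uniform_arc", "flattened_medial", "flattened_lateral"))
    .configError(sprintf("unknown geometry '%s'", geometry))
  geometry <- match.arg(geometry)
  if (nPoints < 5) .configError("nPoints must be >= 5")
  if (arcRadius <= 0) .configError("arcRadius must be > 0")
  s <- seq(-span / 2, span / 2, length.out = nPoints)
  r <- arcRadius
  pts <- switch(geometry,
    uniform_arc = {
      if (span > pi * r + 1e-9) .configError("span exceeds pi * arcRadius")
      cbind(r * sin(s / r), r * (1 - cos(s / r)))
    },
    flattened_medial = {
      w <- flatHalfWidth
      if (w >= span / 2) .geometryError("flatHalfWidth >= span/2: no flank left")
      sa <- pmax(abs(s) - w, 0)        # arc length into the flank
      sgn <- sign(s)
      x <- ifelse(abs(s) <= w, s, sgn * (w + r * sin(sa / r)))
      z <- ifelse(abs(s) <= w, 0, r * (1 - cos(sa / r)))
      cbind(x, z)
    },
    flattened_lateral = {
      w <- flatHalfWidth
      sb <- span / 2 - 2 * w           # breakpoint arc length (left flank)
      if (sb <= 0) .geometryError("flatHalfWidth too large for this span")
      if (span > pi * r + 1e-9) .configError("span exceeds pi * arcRadius")
      x <- r * sin(s / r)
      z <- r * (1 - cos(s / r))
      straight <- s < -sb
      if (any(straight)) {
        thb <- -sb / r
        tb <- c(cos(thb), sin(thb))    # unit tangent at the breakpoint
        x[straight] <- r * sin(thb) + (s[straight] + sb) * tb[1]
        z[straight] <- r * (1 - cos(thb)) + (s[straight] + sb) * tb[2]
      }
      cbind(x, z)
    })
  FoldFront(pts, time = NA_real_, side = "apical")
}

#' Synthetic-study configuration
#'
#' Defaults define the reference in-silico study: 10 animals sharing a
#' medially flattened front (arc radius 300 um, flat half-width 100 um,
#' arc-length span 900 um), a linear tension ramp 0.2 -> 0.6 proxy units
#' over 14-24 hAPF (tension keeps rising through the whole folding period,
#' beyond the 16-22 hAPF imaging window), dissipative prefactor mu = 4e-4
#' (tension x h / um, giving deepening speeds of a few um/h), landmarks
#' every 15 um with 0.5 um Gaussian jitter, frames every 15 min, and
#' ablation-proxy readings every 30 min across 14-24 hAPF with 5%
#' multiplicative log-normal noise.
#'
#' @param nAnimals number of animals (>= 1).
#' @param initialGeometry passed to [makeInitialFront()].
#' @param arcRadius,flatHalfWidth,span geometry parameters (um).
#' @param mu dissipative prefactor (> 0).
#' @param schedule a [TensionSchedule-class].
#' @param landmarkNoiseSd landmark measurement noise sd (um, both coords).
#' @param landmarkSpacing landmark sampling spacing along the front (um).
#' @param frameInterval frame interval (h).
#' @param tStart,tEnd developmental time range (hAPF).
#' @param proxyConstant recoil velocity per unit tension (1 = proxy in
#'   tension units).
#' @param proxyNoiseCv coefficient of variation of the multiplicative
#'   log-normal proxy noise.
#' @param recoilInterval spacing of proxy readings (h).
#' @param recoilTStart,recoilTEnd span of the proxy readings (hAPF); wider
#'   than the imaging window, as ablation series are, so the sliding window
#'   never truncates inside it.
#' @param muCv,tensionCv inter-animal dispersion (CV) of mu and of the
#'   tension scale; 0 by default (no characterized inter-animal variability).
#' @param seed master seed; animal i uses `seed + i`.
#' @param flow a [flowConfig()].
#' @return A validated configuration list of class `study_config`.
#' @export
studyConfig <- function(nAnimals = 10L,
                        initialGeometry = "flattened_medial",
                        arcRadius = 300, flatHalfWidth = 100, span = 900,
                        mu = 4e-4,
                        schedule = makeTensionSchedule("linear_ramp",
                          list(T0 = 0.2, T1 = 0.6, t0 = 14, t1 = 24)),
                        landmarkNoiseSd = 0.5, landmarkSpacing = 15,
                        frameInterval = 0.25, tStart = 16, tEnd = 22,
                        proxyConstant = 1, proxyNoiseCv = 0.05,
                        recoilInterval = 0.5, recoilTStart = 14, recoilTEnd = 24,
                        muCv = 0, tensionCv = 0,
                        seed = 1L, flow = flowConfig()) {
  if (nAnimals < 1) .configError("nAnimals must be >= 1")
  if (tEnd <= tStart) .configError("tEnd must exceed tStart")
  if (mu <= 0) .configError("mu must be > 0")
  if (arcRadius <= 0) .configError("arcRadius must be > 0")
  if (flatHalfWidth < 0) .configError("flatHalfWidth must be >= 0")
  structure(as.list(environment()), class = "study_config")
}

## Resample a noiseless series onto landmark resolution and add iid Gaussian
## jitter to every landmark coordinate.
.landmarkSeries <- function(truthSeries, spacing, noiseSd, seed, id) {
  set.seed(seed)
  fronts <- lapply(seriesFronts(truthSeries), function(f) {
    p <- frontPoints(f)
    L <- .arcLength(p)[nrow(p)]
    nL <- max(5L, round(L / spacing) + 1L)
    q <- frontPoints(resampleFront(f, nL))
    if (noiseSd > 0) q <- q + matrix(rnorm(length(q), 0, noiseSd), ncol = 2)
    FoldFront(q, time = frontTime(f), side = frontSide(f))
  })
  FrontSeries(fronts, animalId = id)
}

#' Simulate one animal: flow forward, sample landmarks, add noise
#'
#' Integrates the curvature-tension flow from `front0`, emits one front per
#' frame, resamples each to landmark spacing and jitters every landmark by
#' independent zero-mean Gaussian offsets in both coordinates. Identical
#' seeds give identical output.
#'
#' @param front0 initial [FoldFront-class].
#' @param schedule a [TensionSchedule-class].
#' @param mu dissipative prefactor (> 0).
#' @param frameInterval frame interval (h, > 0).
#' @param tStart,tEnd time range (hAPF).
#' @param landmarkNoiseSd Gaussian landmark noise sd (um).
#' @param seed integer seed.
#' @param landmarkSpacing landmark spacing (um).
#' @param flow a [flowConfig()].
#' @param animalId identifier.
#' @return list with `series` (noisy landmark [FrontSeries-class]) and
#'   `truth` (noiseless landmark series).
#' @export
simulateAnimal <- function(front0, schedule, mu, frameInterval, tStart, tEnd,
                           landmarkNoiseSd = 0, seed = 1L,
                           landmarkSpacing = 15, flow = flowConfig(),
                           animalId = "animal") {
  if (frameInterval <= 0) .configError("frameInterval must be > 0")
  frameTimes <- seq(tStart, tEnd, by = frameInterval)
  sim <- simulateFlow(front0, schedule, mu, tStart, tEnd, config = flow,
                      frameTimes = frameTimes)
  truth <- .landmarkSeries(sim, landmarkSpacing, 0, seed, animalId)
  series <- .landmarkSeries(sim, landmarkSpacing, landmarkNoiseSd, seed, animalId)
  list(series = series, truth = truth)
}

#' Simulate a multi-animal synthetic study
#'
#' Animal `i` uses seed `config$seed + i`, so subsetting or extending the
#' ensemble never changes an existing animal. The recoil table holds proxy
#' readings `proxyConstant * T(t) * exp(eps)` with `eps` log-normal of unit
#' mean and CV `proxyNoiseCv` (exactly `T(t) * proxyConstant` when the CV
#' is 0). Optional inter-animal dispersion scales each animal's mu and
#' tension by log-normal factors of the configured CVs.
#'
#' @param config a [studyConfig()].
#' @return list with `series` (list of noisy [FrontSeries-class]), `recoil`
#'   (data.frame `animal_id`, `dev_time`, `recoil`), and `truth` (list:
#'   `mu`, `schedule`, `series` of noiseless landmark series, per-animal
#'   `muScale`/`tensionScale`).
#' @export
simulateEnsemble <- function(config) {
  stopifnot(inherits(config, "study_config"))
  front0 <- makeInitialFront(config$initialGeometry, config$arcRadius,
                             config$flatHalfWidth, config$span,
                             nPoints = config$flow$nPoints)
  recoilTimes <- seq(config$recoilTStart, config$recoilTEnd,
                     by = config$recoilInterval)
  seriesList <- vector("list", config$nAnimals)
  truthList <- vector("list", config$nAnimals)
  recoil <- vector("list", config$nAnimals)
  muScale <- numeric(config$nAnimals)
  tenScale <- numeric(config$nAnimals)
  sdlogP <- sqrt(log(1 + config$proxyNoiseCv^2))
  baseSim <- NULL   # animals with identical (mu, tension) share one flow solve
  for (i in seq_len(config$nAnimals)) {
    aSeed <- config$seed + i
    set.seed(aSeed * 2L + 1L)   # dispersion + proxy stream, separate from landmarks
    muScale[i] <- if (config$muCv > 0)
      exp(rnorm(1, -0.5 * log(1 + config$muCv^2), sqrt(log(1 + config$muCv^2)))) else 1
    tenScale[i] <- if (config$tensionCv > 0)
      exp(rnorm(1, -0.5 * log(1 + config$tensionCv^2), sqrt(log(1 + config$tensionCv^2)))) else 1
    eps <- if (config$proxyNoiseCv > 0)
      exp(rnorm(length(recoilTimes), -0.5 * sdlogP^2, sdlogP)) else rep(1, length(recoilTimes))
    id <- sprintf("animal_%02d", i)
    if (muScale[i] == 1 && tenScale[i] == 1) {
      if (is.null(baseSim)) {
        frameTimes <- seq(config$tStart, config$tEnd, by = config$frameInterval)
        baseSim <- simulateFlow(front0, config$schedule, config$mu,
                                config$tStart, config$tEnd,
                                config = config$flow, frameTimes = frameTimes)
      }
      truthList[[i]] <- .landmarkSeries(baseSim, config$landmarkSpacing, 0, aSeed, id)
      seriesList[[i]] <- .landmarkSeries(baseSim, config$landmarkSpacing,
                                         config$landmarkNoiseSd, aSeed, id)
    } else {
      sched <- .scaledSchedule(config$schedule, tenScale[i])
      sim <- simulateAnimal(front0, sched, config$mu * muScale[i],
                            config$frameInterval, config$tStart, config$tEnd,
                            config$landmarkNoiseSd, seed = aSeed,
                            landmarkSpacing = config$landmarkSpacing,
                            flow = config$flow, animalId = id)
      truthList[[i]] <- sim$truth
      seriesList[[i]] <- sim$series
    }
    recoil[[i]] <- data.frame(
      animal_id = id, dev_time = recoilTimes,
      recoil = config$proxyConstant * tenScale[i] *
        tensionAt(config$schedule, recoilTimes) * eps)
  }
  list(series = seriesList,
       recoil = do.call(rbind, recoil),
       truth = list(mu = config$mu, schedule = config$schedule,
                    series = truthList, muScale = muScale, tensionScale = tenScale))
}

.scaledSchedule <- function(schedule, fac) {
  p <- schedule@parameters
  p2 <- switch(schedule@kind,
    constant = list(T0 = p$T0 * fac),
    linear_ramp = list(T0 = p$T0 * fac, T1 = p$T1 * fac, t0 = p$t0, t1 = p$t1),
    piecewise_table = list(times = p$times, tensions = p$tensions * fac))
  makeTensionSchedule(schedule@kind, p2)
}
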