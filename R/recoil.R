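# Laser-ablation recoil analysis: the tension proxy.

#' Initial recoil velocity from an ablation displacement trace
#'
#' Slope of the least-squares line through the displacement samples inside
#' the time window (default: 1-7 s after ablation, the rectangular-ROI
#' convention; circular-ROI traces use 0.25-1.25 s). Recoil velocity
#' indicates tension only up to a dissipation prefactor, so the result is a
#' proxy, never an absolute tension.
#'
#' @param times sample times (s from ablation, strictly increasing, >= 0).
#' @param displacement displacements (um), `displacement[times == 0] = 0` by
#'   convention.
#' @param tStart,tEnd window bounds (s, inclusive).
#' @param method `"regression"` (default, noise-robust) or `"two_point"`
#'   (difference quotient between the interpolated window endpoints; equal
#'   to the regression slope for linear traces).
#' @return Initial recoil velocity (um/s).
#' @export
initialRecoilVelocity <- function(times, displacement, tStart = 1, tEnd = 7,
                                  method = c("regression", "two_point")) {
  method <- match.arg(method)
  if (length(times) != length(displacement)) .configError("length mismatch")
  if (any(diff(times) <= 0) || any(times < 0))
    .dataError("times must be nonnegative and strictly increasing")
  if (method == "two_point") {
    d <- approx(times, displacement, xout = c(tStart, tEnd))$y
    if (any(is.na(d))) .dataError("window not covered by the trace")
    return((d[2] - d[1]) / (tEnd - tStart))
  }
  sel <- times >= tStart - 1e-9 & times <= tEnd + 1e-9
  if (sum(sel) < 2) .dataError("fewer than 2 samples in the fitting window")
  x <- times[sel]; y <- displacement[sel]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Sliding average of measurements over developmental time
#'
#' Centered boxcar mean and sample sd (n-1 denominator) of the values whose
#' dev-times fall within `window / 2` of each evaluation time; the window
#' truncates at the edges of the data, like [smoothTime()].
#'
#' @param devTime,value paired measurements (hAPF, proxy units).
#' @param window full window width (h, default 2).
#' @param evalTimes evaluation times (default: the sorted unique dev-times).
#' @return A [TensionProxyCurve-class] (rows with no in-window measurement
#'   are dropped).
#' @export
slidingAverageByDevTime <- function(devTime, value, window = 2,
                                    evalTimes = NULL) {
  if (!length(devTime)) .dataError("no measurements")
  if (is.null(evalTimes)) evalTimes <- sort(unique(devTime))
  hw <- window / 2 + 1e-9
  rows <- lapply(evalTimes, function(t0) {
    v <- value[abs(devTime - t0) <= hw]
    if (!length(v)) return(NULL)
    data.frame(dev_time = t0, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0, n = length(v))
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) .dataError("no evaluation time has an in-window measurement")
  new("TensionProxyCurve", data = d)
}

#' Assemble a position-resolved tension proxy by initial curvature
#'
#' Positions whose initial curvature lies below the threshold take the
#' tension curve measured in flattened animals (where the corresponding
#' low-curvature regions exist); positions at or above the threshold take
#' the non-flattened curve. The assignment is a pure selection - every
#' output row is copied from one of the two input curves - and is recorded
#' in the `source` column.
#'
#' @param positionCurvatures named numeric vector: initial curvature (1/um)
#'   per Position_ML label.
#' @param flattenedCurve,nonflattenedCurve [TensionProxyCurve-class] objects.
#' @param threshold curvature threshold (1/um, default 0.00015).
#' @return A [TensionProxyCurve-class] with `position_ml` and `source`
#'   columns; positions with missing curvature are omitted with a warning.
#' @export
assembleTensionProxy <- function(positionCurvatures, flattenedCurve,
                                 nonflattenedCurve, threshold = 0.00015) {
  miss <- is.na(positionCurvatures)
  if (any(miss)) {
    warning(sprintf("omitting %d positions with missing initial curvature",
                    sum(miss)))
    positionCurvatures <- positionCurvatures[!miss]
  }
  labs <- names(positionCurvatures)
  if (is.null(labs)) labs <- as.character(seq_along(positionCurvatures))
  rows <- lapply(seq_along(positionCurvatures), function(j) {
    flat <- positionCurvatures[j] < threshold
    d <- curveTable(if (flat) flattenedCurve else nonflattenedCurve)
    d$position_ml <- as.numeric(labs[j])
    d$source <- if (flat) "flattened" else "non_flattened"
    d
  })
  new("TensionProxyCurve", data = do.call(rbind, rows))
}

#' Correlate paired apical and basal recoil velocities
#'
#' @param apical,basal paired values (same animals, same order; >= 3 pairs).
#' @return list with `r` (Pearson), `slope`, `intercept` (ordinary
#'   least-squares basal ~ apical) and `n`. Zero variance in either variable
#'   yields `r = NA` with a warning (undefined-correlation signal).
#' @export
correlateApicalBasal <- function(apical, basal) {
  if (length(apical) != length(basal) || length(apical) < 3)
    .dataError("need >= 3 paired measurements")
  if (var(apical) == 0 || var(basal) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = length(apical)))
  }
  fit <- lm(basal ~ apical)
  list(r = stats::cor(apical, basal), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = length(apical))
}
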