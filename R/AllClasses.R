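#' @import methods
#' @importFrom stats aggregate approx coef lm median oneway.test pt rnorm sd t.test var
#' @importFrom utils read.csv write.csv head tail
NULL

## Classed conditions so callers (and tests) can discriminate failure modes.
.configError <- function(msg) {
  stop(errorCondition(msg, class = c("foldflow_config_error", "error", "condition")))
}
.geometryError <- function(msg) {
  stop(errorCondition(msg, class = c("foldflow_geometry_error", "error", "condition")))
}
.dataError <- function(msg) {
  stop(errorCondition(msg, class = c("foldflow_data_error", "error", "condition")))
}
.simulationError <- function(msg) {
  stop(errorCondition(msg, class = c("foldflow_simulation_error", "error", "condition")))
}

#' FoldFront: a fold-front polyline at one time point
#'
#' An open polyline sampled along the fold front in the transverse plane.
#' Coordinates are `x` (medial-lateral position, um, midline at 0) and `z`
#' (depth, um, positive inward/basal so that deepening increases `z`).
#'
#' @slot time developmental time in hAPF (may be `NA` for static fixtures).
#' @slot points two-column numeric matrix (`x`, `z`), ordered along the front.
#' @slot side `"apical"` or `"basal"`.
#' @exportClass FoldFront
setClass("FoldFront",
  representation(time = "numeric", points = "matrix", side = "character"))

setValidity("FoldFront", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2) return("points must be a numeric n x 2 matrix")
  if (nrow(p) < 3) return("a fold front needs at least 3 points")
  if (any(!is.finite(p))) return("non-finite coordinates")
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg == 0)) return("consecutive points must be distinct")
  if (!object@side %in% c("apical", "basal")) return("side must be 'apical' or 'basal'")
  if (length(object@time) != 1) return("time must be a scalar")
  TRUE
})

#' Construct a FoldFront
#'
#' @param points numeric matrix or data.frame with columns x, z (um).
#' @param time developmental time (hAPF).
#' @param side `"apical"` (default) or `"basal"`.
#' @return A [FoldFront-class] object.
#' @export
FoldFront <- function(points, time = NA_real_, side = "apical") {
  points <- as.matrix(points)
  dimnames(points) <- list(NULL, c("x", "z"))
  new("FoldFront", time = as.numeric(time), points = points, side = side)
}

#' @describeIn FoldFront coordinates as an n x 2 matrix.
#' @param front a `FoldFront`.
#' @export
frontPoints <- function(front) front@points

#' @describeIn FoldFront developmental time (hAPF).
#' @export
frontTime <- function(front) front@time

#' @describeIn FoldFront `"apical"` or `"basal"`.
#' @export
frontSide <- function(front) front@side

setMethod("show", "FoldFront", function(object) {
  cat(sprintf("FoldFront (%s): %d points, t = %s hAPF, ML span [%.1f, %.1f] um\n",
    object@side, nrow(object@points),
    format(object@time), min(object@points[, 1]), max(object@points[, 1])))
})

#' FrontSeries: time-indexed fold fronts for one animal
#'
#' @slot fronts list of [FoldFront-class] objects, strictly increasing in time.
#' @slot animalId identifier.
#' @slot registered whether ML coordinates are landmark-registered.
#' @exportClass FrontSeries
setClass("FrontSeries",
  representation(fronts = "list", animalId = "character", registered = "logical"))

setValidity("FrontSeries", function(object) {
  if (!length(object@fronts)) return("empty series")
  if (!all(vapply(object@fronts, is, logical(1), "FoldFront")))
    return("fronts must be FoldFront objects")
  tt <- vapply(object@fronts, frontTime, numeric(1))
  if (any(is.na(tt)) || any(diff(tt) <= 0)) return("front times must be strictly increasing")
  TRUE
})

#' Construct a FrontSeries
#' @param fronts list of [FoldFront-class] objects (time-sorted).
#' @param animalId identifier string.
#' @param registered logical, landmark-registered coordinates or raw um.
#' @return A [FrontSeries-class] object.
#' @export
FrontSeries <- function(fronts, animalId = "animal", registered = FALSE) {
  new("FrontSeries", fronts = fronts, animalId = animalId, registered = registered)
}

#' @describeIn FrontSeries list of fronts.
#' @param series a `FrontSeries`.
#' @export
seriesFronts <- function(series) series@fronts

#' @describeIn FrontSeries vector of front times (hAPF).
#' @export
seriesTimes <- function(series) vapply(series@fronts, frontTime, numeric(1))

#' @describeIn FrontSeries animal identifier.
#' @export
animalId <- function(series) series@animalId

setMethod("show", "FrontSeries", function(object) {
  tt <- seriesTimes(object)
  cat(sprintf("FrontSeries '%s': %d fronts, t = %.2f..%.2f hAPF%s\n",
    object@animalId, length(object@fronts), min(tt), max(tt),
    if (object@registered) " (registered)" else ""))
})

#' @describeIn FrontSeries number of fronts.
#' @param x a `FrontSeries`.
#' @export
setMethod("length", "FrontSeries", function(x) length(x@fronts))

#' TensionSchedule: in-plane tension versus developmental time
#'
#' Tension is kept in the proxy's units (recoil velocity, um/s) throughout;
#' the collapse-fit slope absorbs the unknown calibration prefactor.
#'
#' @slot kind one of `"constant"`, `"linear_ramp"`, `"piecewise_table"`.
#' @slot parameters named list (see [makeTensionSchedule()]).
#' @exportClass TensionSchedule
setClass("TensionSchedule", representation(kind = "character", parameters = "list"))

setMethod("show", "TensionSchedule", function(object) {
  cat(sprintf("TensionSchedule <%s>\n", object@kind))
})

#' CurvatureSpeedProfile: ensemble curvature/speed measurements
#'
#' Tidy table keyed by (time, position_ml) with ensemble mean curvature,
#' mean normal deepening speed, their standard errors and animal counts.
#'
#' @slot data data.frame with columns `time`, `position_ml`, `kappa`,
#'   `kappa_sem`, `speed`, `speed_sem`, `n_animals`.
#' @slot removedFraction fraction of (time, position) cells dropped by the
#'   coverage and curvature-sem filters.
#' @exportClass CurvatureSpeedProfile
setClass("CurvatureSpeedProfile",
  representation(data = "data.frame", removedFraction = "numeric"))

setValidity("CurvatureSpeedProfile", function(object) {
  need <- c("time", "position_ml", "kappa", "kappa_sem", "speed", "speed_sem", "n_animals")
  if (!all(need %in% names(object@data))) return("missing profile columns")
  d <- object@data
  if (nrow(d) && (any(d$kappa_sem < 0, na.rm = TRUE) || any(d$speed_sem < 0, na.rm = TRUE)))
    return("sems must be nonnegative")
  if (nrow(d) && any(d$n_animals < 1)) return("n_animals must be >= 1")
  TRUE
})

#' @describeIn CurvatureSpeedProfile the underlying tidy data.frame.
#' @param profile a `CurvatureSpeedProfile`.
#' @export
profileTable <- function(profile) profile@data

#' @describeIn CurvatureSpeedProfile fraction of cells removed by filters.
#' @export
removedFraction <- function(profile) profile@removedFraction

setMethod("show", "CurvatureSpeedProfile", function(object) {
  cat(sprintf("CurvatureSpeedProfile: %d (time, position) cells, %.1f%% filtered out\n",
    nrow(object@data), 100 * object@removedFraction))
})

#' TensionProxyCurve: recoil-velocity tension proxy over developmental time
#'
#' @slot data data.frame with columns `dev_time`, `mean`, `sd`, `n` and
#'   optionally `position_ml` and `source` (when assembled per position).
#' @exportClass TensionProxyCurve
setClass("TensionProxyCurve", representation(data = "data.frame"))

setValidity("TensionProxyCurve", function(object) {
  need <- c("dev_time", "mean", "sd", "n")
  if (!all(need %in% names(object@data))) return("missing curve columns")
  if (nrow(object@data) && any(object@data$n < 1)) return("n must be >= 1")
  if (nrow(object@data) && any(object@data$sd < 0, na.rm = TRUE)) return("sd must be >= 0")
  TRUE
})

#' @describeIn TensionProxyCurve the underlying data.frame.
#' @param curve a `TensionProxyCurve`.
#' @export
curveTable <- function(curve) curve@data

setMethod("show", "TensionProxyCurve", function(object) {
  cat(sprintf("TensionProxyCurve: %d rows, t = %.2f..%.2f hAPF\n",
    nrow(object@data), min(object@data$dev_time), max(object@data$dev_time)))
})

#' CollapseDataset: paired (curvature x tension, speed) records
#'
#' @slot records data.frame with columns `time`, `position_ml`, `kappa`,
#'   `kappa_sem`, `tension`, `tension_sd`, `speed`, `speed_sem`, `product`,
#'   `product_sem`.
#' @exportClass CollapseDataset
setClass("CollapseDataset", representation(records = "data.frame"))

setValidity("CollapseDataset", function(object) {
  need <- c("time", "position_ml", "kappa", "kappa_sem", "tension", "tension_sd",
            "speed", "speed_sem", "product", "product_sem")
  if (!all(need %in% names(object@records))) return("missing collapse columns")
  r <- object@records
  if (nrow(r) && max(abs(r$product - r$kappa * r$tension)) > 1e-12 * max(1, max(abs(r$product))))
    return("product must equal kappa * tension")
  TRUE
})

#' @describeIn CollapseDataset the underlying data.frame.
#' @param collapse a `CollapseDataset`.
#' @export
collapseRecords <- function(collapse) collapse@records

setMethod("show", "CollapseDataset", function(object) {
  cat(sprintf("CollapseDataset: %d records\n", nrow(object@records)))
})

#' OriginFit: line-through-origin fit result
#'
#' @slot slope fitted slope (for the collapse, slope corresponds to 1/mu).
#' @slot slopeSd standard deviation of the slope.
#' @slot rSquared coefficient of determination (centered by default).
#' @slot nPoints number of points fitted.
#' @slot weighted whether 1/sem^2 weights were used.
#' @exportClass OriginFit
setClass("OriginFit", representation(
  slope = "numeric", slopeSd = "numeric", rSquared = "numeric",
  nPoints = "integer", weighted = "logical"))

setValidity("OriginFit", function(object) {
  if (object@nPoints < 2) return("n_points must be >= 2")
  TRUE
})

#' @describeIn OriginFit fitted slope.
#' @param fit an `OriginFit`.
#' @export
fitSlope <- function(fit) fit@slope

#' @describeIn OriginFit slope standard deviation.
#' @export
fitSlopeSd <- function(fit) fit@slopeSd

#' @describeIn OriginFit coefficient of determination.
#' @export
fitRSquared <- function(fit) fit@rSquared

setMethod("show", "OriginFit", function(object) {
  cat(sprintf("OriginFit: slope = %.6g +/- %.3g, R^2 = %.4f (n = %d%s)\n",
    object@slope, object@slopeSd, object@rSquared, object@nPoints,
    if (object@weighted) ", weighted" else ""))
})

#' RegistrationFrame: anatomical landmarks for spatial/temporal registration
#'
#' Landmark positions anchoring the Position_ML / Position_AP coordinate
#' systems: the midline maps to 0%, the most posterior/medial head
#' macrochaetae to -100% (left) and +100% (right); along AP the neck-thorax
#' boundary maps to 0% and the anterior scutum macrochaetae to 100%.
#'
#' @slot midlineX,leftMacrochaetaX,rightMacrochaetaX ML landmark positions (um).
#' @slot neckThoraxBoundaryY,scutumMacrochaetaeY AP landmark positions (um).
#' @slot xyTiltDeg,xzTiltDeg deviation of the AP axis from its nominal
#'   orientation in the xy and xz planes (degrees, must be within 15).
#' @slot lastDivisionTime raw clock time of the last microchaete precursor
#'   division (mapped to 22 hAPF).
#' @slot temperatureC acquisition temperature, 25 or 29 (29C intervals are
#'   rescaled by 1.27).
#' @exportClass RegistrationFrame
setClass("RegistrationFrame", representation(
  midlineX = "numeric", leftMacrochaetaX = "numeric", rightMacrochaetaX = "numeric",
  neckThoraxBoundaryY = "numeric", scutumMacrochaetaeY = "numeric",
  xyTiltDeg = "numeric", xzTiltDeg = "numeric",
  lastDivisionTime = "numeric", temperatureC = "numeric"))

setValidity("RegistrationFrame", function(object) {
  if (!(object@leftMacrochaetaX < object@midlineX &&
        object@midlineX < object@rightMacrochaetaX))
    return("landmarks must satisfy left < midline < right")
  if (abs(object@xyTiltDeg) > 15 || abs(object@xzTiltDeg) > 15)
    return("tilt angles above 15 degrees are not correctable")
  TRUE
})

#' Construct a RegistrationFrame
#'
#' @param midlineX,leftMacrochaetaX,rightMacrochaetaX ML landmarks (um).
#' @param neckThoraxBoundaryY,scutumMacrochaetaeY AP landmarks (um).
#' @param xyTiltDeg,xzTiltDeg tilt corrections (degrees, |tilt| <= 15).
#' @param lastDivisionTime raw time of the last microchaete division (h).
#' @param temperatureC 25 or 29.
#' @return A [RegistrationFrame-class] object.
#' @export
RegistrationFrame <- function(midlineX = 0, leftMacrochaetaX = -150,
    rightMacrochaetaX = 150, neckThoraxBoundaryY = 0, scutumMacrochaetaeY = 100,
    xyTiltDeg = 0, xzTiltDeg = 0, lastDivisionTime = NA_real_, temperatureC = 25) {
  new("RegistrationFrame", midlineX = midlineX, leftMacrochaetaX = leftMacrochaetaX,
    rightMacrochaetaX = rightMacrochaetaX, neckThoraxBoundaryY = neckThoraxBoundaryY,
    scutumMacrochaetaeY = scutumMacrochaetaeY, xyTiltDeg = xyTiltDeg,
    xzTiltDeg = xzTiltDeg, lastDivisionTime = lastDivisionTime,
    temperatureC = temperatureC)
}

setMethod("show", "RegistrationFrame", function(object) {
  cat(sprintf("RegistrationFrame: midline %.1f, macrochaetae [%.1f, %.1f] um, %g C\n",
    object@midlineX, object@leftMacrochaetaX, object@rightMacrochaetaX,
    object@temperatureC))
})
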