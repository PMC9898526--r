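# Spatial and temporal registration against anatomical landmarks.

#' Map raw ML positions (um) to Position_ML (%)
#'
#' Per-side affine normalization: the midline maps to 0%, the left
#' macrochaeta to -100% and the right macrochaeta to +100%, with independent
#' scale factors on each side (the landmark triple need not be symmetric).
#'
#' @param x raw ML positions (um).
#' @param frame a [RegistrationFrame-class].
#' @return Position_ML in percent.
#' @export
mlPositionPct <- function(x, frame) {
  m <- frame@midlineX
  dl <- m - frame@leftMacrochaetaX
  dr <- frame@rightMacrochaetaX - m
  if (dl <= 0 || dr <= 0)
    .configError("macrochaetae coincident with (or on the wrong side of) the midline")
  ifelse(x <= m, 100 * (x - m) / dl, 100 * (x - m) / dr)
}

#' Map raw AP positions (um) to Position_AP (%)
#'
#' @param y raw AP positions (um).
#' @param frame a [RegistrationFrame-class].
#' @return Position_AP in percent (boundary 0%, scutum macrochaetae 100%).
#' @export
apPositionPct <- function(y, frame) {
  d <- frame@scutumMacrochaetaeY - frame@neckThoraxBoundaryY
  if (d == 0) .configError("AP landmarks coincide")
  100 * (y - frame@neckThoraxBoundaryY) / d
}

#' Spatially register a front series
#'
#' Applies the in-plane tilt correction (rotation by `-xzTiltDeg` about the
#' midline) and then the per-side affine ML normalization so that x is
#' expressed as Position_ML (%). Depth z stays in um. Registering with an
#' identity frame (midline 0, macrochaetae at the +/-100% scale, zero tilt)
#' is a no-op on already-normalized coordinates.
#'
#' @param series a [FrontSeries-class] with raw um coordinates.
#' @param frame a [RegistrationFrame-class].
#' @return A registered [FrontSeries-class] (x in %, z in um).
#' @export
registerSpace <- function(series, frame) {
  th <- -frame@xzTiltDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fronts <- lapply(seriesFronts(series), function(f) {
    p <- frontPoints(f)
    pc <- sweep(p, 2, c(frame@midlineX, 0))
    pr <- sweep(pc %*% t(R), 2, c(frame@midlineX, 0), `+`)
    pr[, 1] <- mlPositionPct(pr[, 1], frame)
    FoldFront(pr, time = frontTime(f), side = frontSide(f))
  })
  FrontSeries(fronts, animalId = animalId(series), registered = TRUE)
}

#' Temporally register raw clock times to developmental time (hAPF)
#'
#' Raw times are shifted so that the last microchaete precursor division
#' maps to 22 hAPF. Intervals acquired at 29 C are first rescaled by the
#' 1.27 developmental-rate correction; 25 C data are unscaled.
#'
#' @param rawTimes raw clock times (h).
#' @param frame a [RegistrationFrame-class] carrying `lastDivisionTime` and
#'   `temperatureC`.
#' @return Developmental times in hAPF.
#' @export
registerTime <- function(rawTimes, frame) {
  if (is.na(frame@lastDivisionTime))
    .configError("lastDivisionTime missing from registration frame")
  fac <- switch(as.character(frame@temperatureC),
    "25" = 1, "29" = 1.27,
    .configError("unknown acquisition temperature (expected 25 or 29 C)"))
  22 + fac * (rawTimes - frame@lastDivisionTime)
}
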