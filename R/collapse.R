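# The collapse: deepening speed against curvature x tension, and the
# origin-constrained fit whose slope estimates 1/mu.

#' Error of a product of two averaged quantities
#'
#' `sigma_(kappa v) = kappa_mean * sigma_v + v_mean * sigma_kappa +
#' sigma_v * sigma_kappa` - including the cross term.
#'
#' @param kappaMean,kappaErr mean and error of the curvature factor.
#' @param vMean,vErr mean and error of the velocity factor.
#' @return The propagated product error (vectorized).
#' @export
productError <- function(kappaMean, kappaErr, vMean, vErr) {
  if (any(kappaErr < 0) || any(vErr < 0)) .configError("errors must be >= 0")
  abs(kappaMean) * vErr + abs(vMean) * kappaErr + vErr * kappaErr
}

#' Fit a line through the origin
#'
#' `slope = sum(w x y) / sum(w x^2)`; the slope sd comes from the residual
#' variance (n - 1 df). R^2 is computed about the mean of y by default
#' (`centered`; a constant y then gives R^2 <= 0, flagging a poor fit); the
#' uncentered variant (about zero) is available as an option.
#'
#' @param x,y numeric vectors (>= 2 points, not all x zero).
#' @param weights optional weights (e.g. 1/sem^2); unweighted by default
#'   because the collapse is fitted to the ensemble-average values.
#' @param rSquared `"centered"` or `"uncentered"`.
#' @return An [OriginFit-class].
#' @export
fitThroughOrigin <- function(x, y, weights = NULL,
                             rSquared = c("centered", "uncentered")) {
  rSquared <- match.arg(rSquared)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) .dataError("need >= 2 finite points")
  if (all(x == 0)) .dataError("singular fit: all x are zero")
  w <- if (is.null(weights)) rep(1, length(x)) else weights[ok]
  slope <- sum(w * x * y) / sum(w * x^2)
  res <- y - slope * x
  s2 <- sum(w * res^2) / (length(x) - 1)
  slopeSd <- sqrt(s2 / sum(w * x^2))
  ssRes <- sum(w * res^2)
  ssTot <- if (rSquared == "centered") sum(w * (y - sum(w * y) / sum(w))^2)
           else sum(w * y^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else if (ssRes == 0) 1 else -Inf
  new("OriginFit", slope = slope, slopeSd = slopeSd, rSquared = r2,
      nPoints = length(x), weighted = !is.null(weights))
}

#' Join curvature/speed profile with the tension proxy into collapse records
#'
#' Inner join of the ensemble profile and the tension curve on time (and on
#' Position_ML too when the curve is position-resolved); attaches the
#' product `kappa * tension` and its propagated sem via [productError()].
#' Times are matched within `timeTol`.
#'
#' @param profile a [CurvatureSpeedProfile-class].
#' @param tension a [TensionProxyCurve-class].
#' @param timeTol time matching tolerance (h).
#' @return A [CollapseDataset-class] (warns when the join is empty).
#' @export
buildCollapse <- function(profile, tension, timeTol = 1e-6) {
  pd <- profileTable(profile)
  td <- curveTable(tension)
  perPosition <- "position_ml" %in% names(td)
  rows <- lapply(seq_len(nrow(pd)), function(i) {
    cand <- td[abs(td$dev_time - pd$time[i]) <= timeTol, , drop = FALSE]
    if (perPosition)
      cand <- cand[abs(cand$position_ml - pd$position_ml[i]) <= 1e-9, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    j <- which.min(abs(cand$dev_time - pd$time[i]))
    data.frame(time = pd$time[i], position_ml = pd$position_ml[i],
               kappa = pd$kappa[i], kappa_sem = pd$kappa_sem[i],
               tension = cand$mean[j], tension_sd = cand$sd[j],
               speed = pd$speed[i], speed_sem = pd$speed_sem[i])
  })
  rec <- do.call(rbind, rows)
  if (is.null(rec) || !nrow(rec)) {
    warning("empty collapse: no overlapping (time, position) support")
    rec <- data.frame(time = numeric(0), position_ml = numeric(0),
                      kappa = numeric(0), kappa_sem = numeric(0),
                      tension = numeric(0), tension_sd = numeric(0),
                      speed = numeric(0), speed_sem = numeric(0))
  }
  rec$product <- rec$kappa * rec$tension
  rec$product_sem <- productError(rec$kappa, rec$kappa_sem, rec$tension,
                                  rec$tension_sd)
  new("CollapseDataset", records = rec)
}

#' Recover the dissipative prefactor from a collapse dataset
#'
#' Fits speed ~ product through the origin; `mu_hat = 1 / slope`, with the
#' slope sd propagated by the first-order delta method. A nonpositive slope
#' means the data anti-correlate with the Laplace-force prediction: this is
#' signaled (warning, `modelViolation = TRUE`, `muHat = NA`), not thrown, so
#' perturbed scenarios can still be summarized.
#'
#' @param collapse a [CollapseDataset-class].
#' @param weights optional fit weights.
#' @return list with `muHat`, `muSd`, `rSquared`, `fit` (the
#'   [OriginFit-class]) and `modelViolation`.
#' @export
recoverMu <- function(collapse, weights = NULL) {
  rec <- collapseRecords(collapse)
  if (!nrow(rec)) .dataError("empty collapse dataset")
  fit <- fitThroughOrigin(rec$product, rec$speed, weights = weights)
  if (fitSlope(fit) <= 0) {
    warning("model violation: deepening speed anti-correlates with kappa * T")
    return(list(muHat = NA_real_, muSd = NA_real_, rSquared = fitRSquared(fit),
                fit = fit, modelViolation = TRUE))
  }
  list(muHat = 1 / fitSlope(fit),
       muSd = fitSlopeSd(fit) / fitSlope(fit)^2,
       rSquared = fitRSquared(fit), fit = fit, modelViolation = FALSE)
}
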