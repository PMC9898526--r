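# Per-animal curvature/speed profiles and their ensemble aggregation.

#' Centered boxcar smoothing in time
#'
#' Each value is replaced by the mean of all values whose times lie within
#' `window / 2` of its own; at the edges the window simply truncates. A
#' single sample is returned unchanged.
#'
#' @param times sorted numeric times (h).
#' @param values numeric values (NA values are dropped from each window).
#' @param window full window width (h); the default 1.75 is the 1 h 45 min
#'   smoothing used for curvature and deepening speed.
#' @return Smoothed values, same length as the input.
#' @export
smoothTime <- function(times, values, window = 1.75) {
  if (!length(times)) return(numeric(0))
  if (is.unsorted(times)) .configError("times must be sorted")
  hw <- window / 2 + 1e-9
  vapply(seq_along(times), function(i) {
    sel <- abs(times - times[i]) <= hw & !is.na(values)
    if (!any(sel)) NA_real_ else mean(values[sel])
  }, numeric(1))
}

#' Measure per-animal curvature and normal-speed profiles
#'
#' For one animal: track each labeled Position_ML toward the convergence
#' center, then at every frame estimate local curvature (circumcircle on the
#' 22.5 um triplet) and the normal deepening speed to the next frame at the
#' tracked anchor, and finally smooth both in time with the centered boxcar.
#'
#' Pairing of the two estimates (`pairing`):
#' * `"midpoint"` (default): the speed over `[t, t+dt]` is recorded at the
#'   interval midpoint together with the mean of the curvatures at t and
#'   t+dt - unbiased to first order when curvature and tension drift.
#' * `"forward"`: everything recorded at t with the curvature at t.
#'
#' @param series a [FrontSeries-class] (um coordinates).
#' @param center convergence center `c(x, z)` (um).
#' @param anchorX tracked ML positions (um) read off the first front.
#' @param labels labels for the anchors (e.g. Position_ML %).
#' @param halfSpan triplet half-span (um).
#' @param smoothWindow boxcar width (h); 0 disables smoothing.
#' @param pairing `"midpoint"` or `"forward"`.
#' @return data.frame with `animal_id`, `time`, `position_ml`, `kappa`,
#'   `speed` (NA rows dropped).
#' @export
measureProfiles <- function(series, center, anchorX, labels = anchorX,
                            halfSpan = 22.5, smoothWindow = 1.75,
                            pairing = c("midpoint", "forward")) {
  pairing <- match.arg(pairing)
  fronts <- seriesFronts(series)
  tt <- seriesTimes(series)
  m <- length(fronts)
  if (m < 2) .configError("need at least two frames to measure speed")
  traj <- trackTowardCenter(series, center, anchorX, labels)
  out <- vector("list", length(labels))
  for (j in seq_along(labels)) {
    tj <- traj[traj$label == labels[j] & !traj$truncated, ]
    if (!nrow(tj)) next
    sAt <- function(i) {
      r <- tj[abs(tj$time - tt[i]) < 1e-9, "s"]
      if (length(r)) r[1] else NA_real_
    }
    kap <- spd <- tms <- rep(NA_real_, m - 1)
    for (i in seq_len(m - 1)) {
      s0 <- sAt(i)
      if (is.na(s0)) next
      k0 <- localCurvature(fronts[[i]], s0, halfSpan)
      v0 <- normalSpeed(fronts[[i]], fronts[[i + 1]], s0, halfSpan)
      if (pairing == "midpoint") {
        s1 <- sAt(i + 1)
        k1 <- if (is.na(s1)) NA_real_ else localCurvature(fronts[[i + 1]], s1, halfSpan)
        kap[i] <- mean(c(k0, k1), na.rm = TRUE)
        tms[i] <- (tt[i] + tt[i + 1]) / 2
      } else {
        kap[i] <- k0
        tms[i] <- tt[i]
      }
      spd[i] <- v0
    }
    ok <- !is.na(tms)
    if (!any(ok)) next
    if (smoothWindow > 0) {
      kap[ok] <- smoothTime(tms[ok], kap[ok], smoothWindow)
      spd[ok] <- smoothTime(tms[ok], spd[ok], smoothWindow)
    }
    out[[j]] <- data.frame(animal_id = animalId(series), time = tms[ok],
                           position_ml = labels[j], kappa = kap[ok],
                           speed = spd[ok])
  }
  res <- do.call(rbind, out)
  res[!is.na(res$kappa) & !is.na(res$speed), ]
}

#' Average per-animal profiles into an ensemble profile
#'
#' Means and standard errors (sd / sqrt(n), n = contributing animals) per
#' (time, Position_ML) cell. Cells sampled in fewer than `minAnimals`
#' animals, or whose curvature sem exceeds `maxCurvatureSem`, are removed;
#' the removed fraction is recorded on the result.
#'
#' @param profiles data.frame from [measureProfiles()] rows of all animals
#'   (or a list of such data.frames).
#' @param minAnimals minimum animal coverage (default 5).
#' @param maxCurvatureSem curvature-sem cutoff (1/um, default 0.002).
#' @return A [CurvatureSpeedProfile-class]. Warns (not errors) when every
#'   cell is filtered out.
#' @export
ensembleAverage <- function(profiles, minAnimals = 5, maxCurvatureSem = 0.002) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, profiles)
  if (!nrow(profiles)) .dataError("no profile rows to average")
  key <- paste(round(profiles$time, 9), round(profiles$position_ml, 9), sep = "|")
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  agg <- do.call(rbind, lapply(split(profiles, key), function(d) {
    data.frame(time = d$time[1], position_ml = d$position_ml[1],
               kappa = mean(d$kappa), kappa_sem = sem(d$kappa),
               speed = mean(d$speed), speed_sem = sem(d$speed),
               n_animals = length(unique(d$animal_id)))
  }))
  keep <- agg$n_animals >= minAnimals & agg$kappa_sem <= maxCurvatureSem
  removed <- 1 - sum(keep) / nrow(agg)
  if (!any(keep)) warning("all (time, position) cells removed by the filters")
  agg <- agg[keep, , drop = FALSE]
  agg <- agg[order(agg$time, agg$position_ml), ]
  rownames(agg) <- NULL
  new("CurvatureSpeedProfile", data = agg, removedFraction = removed)
}
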