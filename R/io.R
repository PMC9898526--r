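# File I/O: fronts and recoil tables as tidy CSV, profiles/fits as CSV/JSON,
# images as TIFF.

#' Write front series to tidy CSV
#'
#' Columns: `animal_id`, `time_hAPF`, `point_index`, `x_um`, `z_um`.
#'
#' @param seriesList a [FrontSeries-class] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFrontsCsv <- function(seriesList, path) {
  if (is(seriesList, "FrontSeries")) seriesList <- list(seriesList)
  rows <- lapply(seriesList, function(s) {
    do.call(rbind, lapply(seriesFronts(s), function(f) {
      p <- frontPoints(f)
      data.frame(animal_id = animalId(s), time_hAPF = frontTime(f),
                 point_index = seq_len(nrow(p)), x_um = p[, 1], z_um = p[, 2])
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read front series from tidy CSV
#'
#' @param path CSV written by [writeFrontsCsv()].
#' @param side front side label for the loaded polylines.
#' @return Named list of [FrontSeries-class], one per `animal_id`.
#' @export
readFrontsCsv <- function(path, side = "apical") {
  d <- read.csv(path)
  need <- c("animal_id", "time_hAPF", "point_index", "x_um", "z_um")
  if (!all(need %in% names(d))) .dataError("missing front CSV columns")
  lapply(split(d, d$animal_id), function(da) {
    fronts <- lapply(split(da, da$time_hAPF), function(df) {
      df <- df[order(df$point_index), ]
      FoldFront(cbind(df$x_um, df$z_um), time = df$time_hAPF[1], side = side)
    })
    fronts <- unname(fronts[order(vapply(fronts, frontTime, numeric(1)))])
    FrontSeries(fronts, animalId = as.character(da$animal_id[1]))
  })
}

#' Write an ensemble profile to tidy CSV
#'
#' Columns: `time_hAPF`, `position_ml_pct`, `curvature_per_um`,
#' `curvature_sem`, `speed_um_per_h`, `speed_sem`, `n_animals`.
#'
#' @param profile a [CurvatureSpeedProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfileCsv <- function(profile, path) {
  d <- profileTable(profile)
  out <- data.frame(time_hAPF = d$time, position_ml_pct = d$position_ml,
                    curvature_per_um = d$kappa, curvature_sem = d$kappa_sem,
                    speed_um_per_h = d$speed, speed_sem = d$speed_sem,
                    n_animals = d$n_animals)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a recoil table CSV
#'
#' Expected columns: `animal_id`, `dev_time`, `recoil` (or the trace dialect
#' `animal_id`, `dev_time_hAPF`, `t_s`, `displacement_um`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readRecoilCsv <- function(path) {
  d <- read.csv(path)
  if (all(c("animal_id", "dev_time", "recoil") %in% names(d))) return(d)
  if (all(c("animal_id", "dev_time_hAPF", "t_s", "displacement_um") %in% names(d)))
    return(d)
  .dataError("unrecognized recoil CSV columns")
}

#' Write an image or stack as TIFF
#'
#' @param image matrix or 3D array `[x, y, z]` (written as a multi-page TIFF).
#' @param path output path.
#' @param scale divide by this before writing (TIFF stores [0, 1]).
#' @return `path`, invisibly.
#' @export
writeImageTiff <- function(image, path, scale = max(abs(image), 1)) {
  img <- image / scale
  if (length(dim(image)) == 3) {
    pages <- lapply(seq_len(dim(img)[3]), function(z) t(img[, , z]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(t(img), path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a TIFF image or stack
#'
#' @param path TIFF path.
#' @return matrix (single page) or 3D array `[x, y, z]`.
#' @export
readImageTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1) return(t(pages[[1]]))
  arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
  arr
}

#' Write an origin-fit summary as JSON
#'
#' @param fitSummary list from [recoverMu()] (the `fit` element is expanded).
#' @param path output path.
#' @param extra optional named list merged into the document.
#' @return `path`, invisibly.
#' @export
writeFitJson <- function(fitSummary, path, extra = list()) {
  doc <- c(list(mu_hat = fitSummary$muHat, mu_sd = fitSummary$muSd,
                slope = fitSlope(fitSummary$fit),
                slope_sd = fitSlopeSd(fitSummary$fit),
                r_squared = fitSummary$rSquared,
                n_points = fitSummary$fit@nPoints,
                model_violation = fitSummary$modelViolation),
           extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
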