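# End-to-end driver: synthetic study (or CSV inputs) -> profiles -> tension
# proxy -> collapse -> origin fit -> summary bundle.

#' Run the full curvature-tension analysis
#'
#' Executes the measurement pipeline on a synthetic study (or on front /
#' recoil tables loaded from CSV): material tracking toward the convergence
#' center, triplet curvature and normal-speed profiles with temporal
#' smoothing, ensemble averaging with the coverage and curvature-sem
#' filters, the 2 h sliding tension proxy, the collapse join, and the
#' origin-constrained fit recovering the dissipative prefactor mu. The run
#' is deterministic given the configuration (all randomness is seeded from
#' `config$seed`).
#'
#' @param config a [studyConfig()], or a list with elements `frontsCsv`,
#'   `recoilCsv`, `center`, `anchorX`, `labels` (+ optional `mlPctPerUm`).
#' @param outputDir optional directory; when given, writes `profile.csv`,
#'   `collapse.csv`, `fit.json` and `log.txt`.
#' @param pairing passed to [measureProfiles()].
#' @param anchorStepPct spacing of tracked Position_ML labels (%, default 10).
#' @param minAnimals,maxCurvatureSem ensemble filters, see [ensembleAverage()].
#' @param anchorMarginUm for synthetic studies, minimum distance (um) kept
#'   between tracked anchors and the pinned ends of the simulated strip.
#' @return list with `profile` ([CurvatureSpeedProfile-class]), `tension`
#'   ([TensionProxyCurve-class]), `collapse` ([CollapseDataset-class]),
#'   `fit` (from [recoverMu()]), `depth` (data.frame), and `log`
#'   (character vector of stage lines).
#' @export
runPipeline <- function(config, outputDir = NULL,
                        pairing = c("midpoint", "forward"),
                        anchorStepPct = 10, minAnimals = 5,
                        maxCurvatureSem = 0.002, anchorMarginUm = 225) {
  pairing <- match.arg(pairing)
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    invisible(line)
  }
  if (inherits(config, "study_config")) {
    say("stage=simulate n_animals=%d seed=%d geometry=%s", config$nAnimals,
        config$seed, config$initialGeometry)
    ens <- simulateEnsemble(config)
    seriesList <- ens$series
    recoil <- ens$recoil
    center <- c(0, config$arcRadius)
    pctPerUm <- 100 / 150   # synthetic macrochaetae at +/-150 um = +/-100%
    ## anchors keep a buffer from the pinned simulation edges: the pins are
    ## an artifact of the finite simulated strip, and their influence spreads
    ## diffusively, sqrt(2 (T/mu) t) ~ 110 um over a 6 h run; two diffusion
    ## lengths (225 um) keep the tracked region clean
    maxPct <- floor(pctPerUm * (config$span / 2 - anchorMarginUm) /
                    anchorStepPct) * anchorStepPct
    if (maxPct < anchorStepPct)
      .configError("anchorMarginUm leaves no tracked positions")
    labels <- seq(-maxPct, maxPct, by = anchorStepPct)
    anchorX <- labels / pctPerUm
  } else {
    if (is.null(config$frontsCsv) || is.null(config$center))
      .configError("config must provide frontsCsv and center (see neckDepth for the reference-front requirement)")
    say("stage=load fronts=%s", config$frontsCsv)
    seriesList <- readFrontsCsv(config$frontsCsv)
    recoil <- if (!is.null(config$recoilCsv)) readRecoilCsv(config$recoilCsv) else NULL
    center <- config$center
    anchorX <- config$anchorX
    labels <- if (is.null(config$labels)) anchorX else config$labels
  }
  profiles <- lapply(seriesList, function(s)
    measureProfiles(s, center, anchorX, labels, pairing = pairing))
  say("stage=geometry animals=%d rows=%d", length(profiles),
      sum(vapply(profiles, nrow, integer(1))))
  profile <- ensembleAverage(profiles, minAnimals = minAnimals,
                             maxCurvatureSem = maxCurvatureSem)
  say("stage=ensemble cells=%d removed_fraction=%.4f",
      nrow(profileTable(profile)), removedFraction(profile))
  tension <- slidingAverageByDevTime(recoil$dev_time, recoil$recoil,
                                     evalTimes = sort(unique(profileTable(profile)$time)))
  say("stage=recoil rows=%d", nrow(curveTable(tension)))
  collapse <- buildCollapse(profile, tension)
  say("stage=collapse records=%d", nrow(collapseRecords(collapse)))
  fit <- recoverMu(collapse)
  say("stage=fit slope=%.6g r2=%.4f mu_hat=%.6g", fitSlope(fit$fit),
      fit$rSquared, fit$muHat)
  depth <- tryCatch(
    neckDepth(seriesList[[1]], center, anchorX, labels,
              referenceTime = min(seriesTimes(seriesList[[1]]))),
    error = function(e) NULL)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeProfileCsv(profile, file.path(outputDir, "profile.csv"))
    write.csv(collapseRecords(collapse), file.path(outputDir, "collapse.csv"),
              row.names = FALSE)
    writeFitJson(fit, file.path(outputDir, "fit.json"),
                 extra = list(r_version = as.character(getRversion())))
    writeLines(log, file.path(outputDir, "log.txt"))
  }
  list(profile = profile, tension = tension, collapse = collapse, fit = fit,
       depth = depth, log = log)
}
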