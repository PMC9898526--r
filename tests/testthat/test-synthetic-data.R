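test_that("uniform arc geometry puts every point on the stated circle", {
  f <- makeInitialFront("uniform_arc", arcRadius = 300, span = 600, nPoints = 101)
  p <- frontPoints(f)
  expect_lt(max(abs(sqrt(p[, 1]^2 + (p[, 2] - 300)^2) - 300)), 1e-9)
  seg <- sqrt(rowSums((p[-1, ] - p[-101, ])^2))
  expect_lt(diff(range(seg)) / mean(seg), 1e-9)  # uniform spacing
})

test_that("medially flattened geometry has an exactly flat interior and curved flanks", {
  f <- makeInitialFront("flattened_medial", arcRadius = 300, flatHalfWidth = 100,
                        span = 900, nPoints = 181)
  # arc-length of the apex is span/2 = 450; |x| <= 77.5 um keeps the whole
  # 22.5 um triplet inside the flat segment (the boundary anchor's flank
  # lands within chord-shortening distance of the junction, hence the 1e-7)
  expect_identical(localCurvature(f, c(450 - 50, 450, 450 + 50)), c(0, 0, 0))
  expect_lt(max(abs(localCurvature(f, c(450 - 77.5, 450 + 77.5)))), 1e-6)
  kFlank <- localCurvature(f, c(150, 250, 650, 750))
  expect_equal(kFlank, rep(1 / 300, 4), tolerance = 0.02)
})

test_that("huge radius degenerates to a straight line", {
  # at r = 1e12 um the sagitta over a 600 um span is span^2/(8r) ~ 5e-8 um
  f <- makeInitialFront("uniform_arc", arcRadius = 1e12, span = 600, nPoints = 51)
  p <- frontPoints(f)
  # distance of every point from the chord through the endpoints
  a <- p[1, ]; b <- p[nrow(p), ]
  u <- (b - a) / sqrt(sum((b - a)^2))
  d <- abs((p[, 1] - a[1]) * u[2] - (p[, 2] - a[2]) * u[1])
  expect_lt(max(d), 1e-6)
})

test_that("laterally flattened geometry straightens one flank only", {
  f <- makeInitialFront("flattened_lateral", arcRadius = 300, flatHalfWidth = 100,
                        span = 900, nPoints = 181)
  expect_lt(abs(localCurvature(f, 50)), 1e-12)          # straightened left end
  expect_equal(localCurvature(f, 700), 1 / 300, tolerance = 0.02)  # intact right flank
})

test_that("geometry construction rejects invalid configurations", {
  expect_error(makeInitialFront("banana"), class = "foldflow_config_error")
  expect_error(makeInitialFront("flattened_medial", flatHalfWidth = 500, span = 900),
               class = "foldflow_geometry_error")
  expect_error(makeInitialFront("uniform_arc", arcRadius = 100, span = 600),
               class = "foldflow_config_error")  # span > pi r
  expect_error(makeInitialFront("uniform_arc", nPoints = 4),
               class = "foldflow_config_error")
})

test_that("tension schedules evaluate, interpolate, and clamp", {
  expect_equal(tensionAt(makeTensionSchedule("constant", list(T0 = 0.5)), 19.3), 0.5)
  ramp <- makeTensionSchedule("linear_ramp", list(T0 = 0.2, T1 = 0.6, t0 = 18, t1 = 24))
  expect_equal(tensionAt(ramp, 21), 0.4)
  expect_equal(tensionAt(ramp, 30), 0.6)   # clamped above
  expect_equal(tensionAt(ramp, 10), 0.2)   # clamped below
  tab <- makeTensionSchedule("piecewise_table",
                             list(times = c(16, 20, 24), tensions = c(0.1, 0.5, 0.5)))
  expect_equal(tensionAt(tab, 18), 0.3)
  expect_error(makeTensionSchedule("constant", list(T0 = -1)),
               class = "foldflow_config_error")
  expect_error(makeTensionSchedule("piecewise_table",
                                   list(times = c(1, 1), tensions = c(0, 0))),
               class = "foldflow_config_error")
})

test_that("zero tension leaves simulated fronts identical across frames", {
  f0 <- makeInitialFront("uniform_arc", 300, span = 600, nPoints = 61)
  sched0 <- makeTensionSchedule("constant", list(T0 = 0))
  sim <- simulateAnimal(f0, sched0, mu = 1, frameInterval = 0.5,
                        tStart = 16, tEnd = 18, landmarkNoiseSd = 0, seed = 1)
  pts <- lapply(seriesFronts(sim$series), frontPoints)
  for (p in pts[-1]) expect_equal(p, pts[[1]], tolerance = 1e-12)
})

test_that("identical seeds give bitwise-identical landmark tables", {
  f0 <- makeInitialFront("uniform_arc", 300, span = 600, nPoints = 61)
  sched <- makeTensionSchedule("constant", list(T0 = 0.3))
  a <- simulateAnimal(f0, sched, 4e-4, 0.5, 16, 17, landmarkNoiseSd = 0.5, seed = 99)
  b <- simulateAnimal(f0, sched, 4e-4, 0.5, 16, 17, landmarkNoiseSd = 0.5, seed = 99)
  expect_identical(lapply(seriesFronts(a$series), frontPoints),
                   lapply(seriesFronts(b$series), frontPoints))
})

test_that("noise-free ensembles are identical across animals and proxies exact", {
  cfg <- studyConfig(nAnimals = 3, landmarkNoiseSd = 0, proxyNoiseCv = 0,
                     tEnd = 17, seed = 5)
  ens <- simulateEnsemble(cfg)
  p1 <- lapply(seriesFronts(ens$series[[1]]), frontPoints)
  for (s in ens$series[-1])
    expect_equal(lapply(seriesFronts(s), frontPoints), p1, tolerance = 1e-12)
  expect_equal(ens$recoil$recoil, tensionAt(cfg$schedule, ens$recoil$dev_time))
})

test_that("raising the ensemble size never changes an existing animal", {
  cfg3 <- studyConfig(nAnimals = 3, tEnd = 17, seed = 11)
  cfg5 <- studyConfig(nAnimals = 5, tEnd = 17, seed = 11)
  e3 <- simulateEnsemble(cfg3)
  e5 <- simulateEnsemble(cfg5)
  expect_identical(lapply(seriesFronts(e3$series[[2]]), frontPoints),
                   lapply(seriesFronts(e5$series[[2]]), frontPoints))
  expect_identical(e3$recoil$recoil[e3$recoil$animal_id == "animal_02"],
                   e5$recoil$recoil[e5$recoil$animal_id == "animal_02"])
})

test_that("landmark noise is calibrated to the requested sd", {
  f0 <- makeInitialFront("uniform_arc", 3000, span = 9000, nPoints = 301)
  sched0 <- makeTensionSchedule("constant", list(T0 = 0))
  noisy <- simulateAnimal(f0, sched0, 1, 0.25, 16, 22, landmarkNoiseSd = 0.5,
                          seed = 3, landmarkSpacing = 15)
  clean <- simulateAnimal(f0, sched0, 1, 0.25, 16, 22, landmarkNoiseSd = 0,
                          seed = 3, landmarkSpacing = 15)
  d <- mapply(function(a, b) frontPoints(a) - frontPoints(b),
              seriesFronts(noisy$series), seriesFronts(clean$series))
  d <- unlist(d)
  expect_gt(length(d), 2e4)
  expect_equal(sd(d), 0.5, tolerance = 0.05)
})

test_that("synthetic recoil traces follow the viscoelastic closed form", {
  tr <- synthRecoilTrace(v0 = 1, tau = 1e9, duration = 30, dt = 1)
  expect_equal(tr$displacement, tr$time, tolerance = 1e-6)  # pure linear recoil
  tr2 <- synthRecoilTrace(v0 = 0.5, tau = 10, duration = 30, dt = 1)
  expect_equal(tr2$displacement[tr2$time == 7] - tr2$displacement[tr2$time == 1],
               0.5 * 10 * (exp(-0.1) - exp(-0.7)))
  expect_equal(tr2$displacement[1], 0)
  a <- synthRecoilTrace(1, 5, noiseSd = 0, seed = 1)
  b <- synthRecoilTrace(1, 5, noiseSd = 0, seed = 2)
  expect_identical(a, b)   # seed only affects noise
  expect_error(synthRecoilTrace(1, 5, dt = 0), class = "foldflow_config_error")
})

test_that("fiber images record folded orientations and reject out-of-bounds bars", {
  fi <- synthFiberImage(data.frame(cx = 10, cy = 10, angle = 150, length = 5,
                                   width = 0.5, intensity = 50))
  expect_equal(fi$truth$orientation, 30)  # fold rule: min(theta, 180 - theta)
  expect_equal(fi$truth$length, 5)
  fi0 <- synthFiberImage(NULL, imageSize = c(32, 32), background = 7)
  expect_true(all(fi0$image == 7))
  expect_identical(nrow(fi0$truth), 0L)
  expect_error(synthFiberImage(data.frame(cx = 1, cy = 1, angle = 0, length = 50,
                                          width = 0.5, intensity = 1),
                               imageSize = c(64, 64)),
               class = "foldflow_config_error")
})

test_that("z-stacks put the signal bump at the requested height", {
  st <- synthZStack(matrix(20, 8, 8), nSlices = 40)
  am <- apply(st, c(1, 2), which.max)
  expect_true(all(am == 20))
  hm <- matrix(rep(seq(10, 30, length.out = 8), each = 8), 8, 8)
  st2 <- synthZStack(hm, nSlices = 40)
  am2 <- apply(st2, c(1, 2), which.max)
  expect_true(all(abs(am2 - hm) <= 0.51))
  # arbitrarily noisy stacks are still valid generator output
  st3 <- synthZStack(matrix(20, 4, 4), nSlices = 30, signalAmplitude = 1,
                     noiseSd = 50, seed = 2)
  expect_identical(dim(st3), c(4L, 4L, 30L))
  expect_error(synthZStack(matrix(99, 2, 2), nSlices = 30),
               class = "foldflow_config_error")
})
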