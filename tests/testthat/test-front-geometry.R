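test_that("resampling is uniform, on-curve, and endpoint-preserving", {
  seg <- FoldFront(cbind(seq(0, 10, length.out = 4), 0))
  r <- resampleFront(seg, 11)
  expect_equal(frontPoints(r)[, 1], 0:10)
  expect_equal(frontPoints(r)[, 2], rep(0, 11))

  qc <- openArc(100, span = 100 * pi / 2, n = 21)   # quarter circle, coarse
  r2 <- resampleFront(qc, 201)
  p <- frontPoints(r2)
  expect_lt(max(abs(sqrt(p[, 1]^2 + (p[, 2] - 100)^2) - 100)), 0.1)
  sp <- sqrt(rowSums((p[-1, ] - p[-201, ])^2))
  expect_lt(diff(range(sp)) / mean(sp), 1e-6)

  r3 <- resampleFront(qc, 3)
  p3 <- frontPoints(r3)
  expect_equal(p3[c(1, 3), ], frontPoints(qc)[c(1, 21), ])
  cs <- cumsum(c(0, sqrt(rowSums(diff(p3)^2))))
  expect_equal(cs[2], cs[3] / 2, tolerance = 1e-9)  # arc-length midpoint
})

test_that("resampling preserves total arc length on convex fronts", {
  arc <- openArc(300, span = 600, n = 400)
  for (n in c(50, 123, 800)) {
    r <- resampleFront(arc, n)
    L0 <- sum(sqrt(rowSums(diff(frontPoints(arc))^2)))
    L1 <- sum(sqrt(rowSums(diff(frontPoints(r))^2)))
    expect_lt(abs(L1 - L0) / L0, 1e-3)   # chords of the chord polyline
  }
  # resampling its own output is length-stable to 1e-6
  r1 <- resampleFront(arc, 400)
  r2 <- resampleFront(r1, 400)
  L1 <- sum(sqrt(rowSums(diff(frontPoints(r1))^2)))
  L2 <- sum(sqrt(rowSums(diff(frontPoints(r2))^2)))
  expect_lt(abs(L2 - L1) / L1, 1e-6)
})

test_that("circumcircle curvature is exact on circles and signed by center side", {
  # triplet on a circle of radius 300 with center at +z
  th <- c(-0.2, 0.05, 0.3)
  pts <- lapply(th, function(a) c(300 * sin(a), 300 - 300 * cos(a)))
  expect_equal(circumcircleCurvature(pts[[1]], pts[[2]], pts[[3]]), 1 / 300,
               tolerance = 1e-12)
  # center at -z flips the sign
  ptsNeg <- lapply(pts, function(p) c(p[1], -p[2]))
  expect_equal(circumcircleCurvature(ptsNeg[[1]], ptsNeg[[2]], ptsNeg[[3]]),
               -1 / 300, tolerance = 1e-12)
  # collinear triplet: exactly zero
  expect_identical(circumcircleCurvature(c(0, 0), c(1, 1), c(3, 3)), 0)
})

test_that("local curvature drops positions within half a span of the ends", {
  arc <- openArc(300, span = 600, n = 201)
  expect_true(is.na(localCurvature(arc, 10)))
  expect_true(is.na(localCurvature(arc, 595)))
  expect_false(is.na(localCurvature(arc, 22.5)))
})

test_that("curvature error on an ellipse shrinks quadratically with the span", {
  a <- 300; b <- 200
  th <- seq(0, pi, length.out = 2001)
  ell <- FoldFront(cbind(a * cos(th), b * sin(th)))
  kTrue <- function(t) a * b / (a^2 * sin(t)^2 + b^2 * cos(t)^2)^1.5
  cs <- cumsum(c(0, sqrt(rowSums(diff(frontPoints(ell))^2))))
  iProbe <- seq(300, 1700, by = 100)
  err <- function(h) {
    k <- localCurvature(ell, cs[iProbe], halfSpan = h)
    max(abs(abs(k) - kTrue(th[iProbe])))
  }
  e1 <- err(22.5); e2 <- err(11.25)
  expect_gt(e1 / e2, 2.5)   # ~4x for an O(h^2) estimator
  expect_lt(e1 / e2, 6.5)
})

test_that("normal deepening speed matches translation, concentric shrink, and rest", {
  flat1 <- FoldFront(cbind(seq(-50, 50, 5), 0), time = 16)
  flat2 <- FoldFront(cbind(seq(-50, 50, 5), 5), time = 16.25)
  v <- normalSpeed(flat1, flat2, c(30, 50, 70))
  expect_equal(v, rep(20, 3))              # 5 um in 0.25 h, everywhere

  c1 <- openArc(100, span = 150, n = 801, time = 0)
  c2 <- openArc(95, span = 150 * 0.95, n = 801, time = 1, center = c(0, 100))
  expect_equal(normalSpeed(c1, c2, c(40, 75, 110)), rep(5, 3), tolerance = 1e-3)

  expect_equal(normalSpeed(flat1, FoldFront(frontPoints(flat1), time = 17), 50), 0)
})

test_that("normal speed signals a missing value when the normal misses the front", {
  f1 <- FoldFront(cbind(seq(-50, 50, 5), 0), time = 0)
  f2 <- FoldFront(cbind(seq(200, 260, 5), 5), time = 1)  # disjoint support
  expect_true(is.na(normalSpeed(f1, f2, 50)))
})

test_that("time smoothing is a truncated centered boxcar", {
  tt <- seq(0, 5, by = 0.25)
  expect_equal(smoothTime(tt, rep(3, length(tt))), rep(3, length(tt)))
  expect_equal(smoothTime(1.5, 7), 7)      # single sample
  v <- rep(0, length(tt)); v[9] <- 8       # t = 2.0
  sm <- smoothTime(tt, v, window = 1.75)
  expect_equal(sm[9], 8 / 7)               # 7 frames inside +/- 0.875 h
})

test_that("ensemble averaging applies the coverage and curvature-sem filters", {
  mk <- function(animal, pos, kap) {
    data.frame(animal_id = animal, time = 20, position_ml = pos,
               kappa = kap, speed = 1)
  }
  # position 0: 5 animals, tight; position 50: only 4 animals;
  # position 100: 5 animals with inflated curvature spread (sem > 0.002)
  rows <- rbind(
    do.call(rbind, lapply(1:5, function(i) mk(i, 0, 0.003 + 1e-4 * i))),
    do.call(rbind, lapply(1:4, function(i) mk(i, 50, 0.003))),
    do.call(rbind, lapply(1:5, function(i) mk(i, 100, 0.004 * i))))  # sem ~ 0.0028
  prof <- ensembleAverage(rows, minAnimals = 5, maxCurvatureSem = 0.002)
  d <- profileTable(prof)
  expect_identical(d$position_ml, 0)
  expect_equal(removedFraction(prof), 2 / 3)
  # N identical animals: sem exactly 0, nothing excluded
  same <- do.call(rbind, lapply(1:10, function(i) mk(i, 0, 0.0031)))
  d2 <- profileTable(ensembleAverage(same))
  expect_equal(d2$kappa_sem, 0)
  expect_equal(d2$kappa, 0.0031)
  expect_identical(d2$n_animals, 10L)
})

test_that("tracking toward a center follows radii on concentric circles", {
  fronts <- lapply(0:4, function(i) {
    openArc(300 - 10 * i, span = (300 - 10 * i) * 2, n = 301, time = 16 + i,
            center = c(0, 300))
  })
  ser <- FrontSeries(fronts)
  traj <- trackTowardCenter(ser, c(0, 300), anchorX = c(-100, 0, 100))
  for (lab in c(-100, 0, 100)) {
    tj <- traj[traj$label == lab, ]
    expect_false(any(tj$truncated))
    # all trajectory points on the ray from the initial point to the center
    d0 <- c(tj$x[1], tj$z[1] - 300)
    cr <- tj$x * d0[2] - (tj$z - 300) * d0[1]
    expect_lt(max(abs(cr)), 1e-6 * 300)
  }
  # stationary front: the trajectory stays at one point
  still <- FrontSeries(lapply(16:18, function(t) openArc(300, 600, 101, time = t)))
  tj <- trackTowardCenter(still, c(0, 300), 50)
  expect_lt(max(dist(cbind(tj$x, tj$z))), 1e-9)
})

test_that("near-midline trajectories of a descending straight front are near-vertical", {
  fronts <- lapply(0:3, function(i)
    FoldFront(cbind(seq(-200, 200, 10), 10 * i), time = 16 + i))
  ser <- FrontSeries(fronts)
  traj <- trackTowardCenter(ser, c(0, 1e5), anchorX = c(-20, 20))
  for (lab in c(-20, 20)) {
    tj <- traj[traj$label == lab, ]
    expect_lt(max(abs(tj$x - tj$x[1])), 0.05)  # < 50 nm lateral drift
    expect_equal(tj$z, c(0, 10, 20, 30), tolerance = 1e-6)
  }
})

test_that("neck depth is the averaged tracked displacement from the reference front", {
  fronts <- lapply(0:3, function(i)
    FoldFront(cbind(seq(-400, 400, 10), 12 * i), time = 16 + i))
  ser <- FrontSeries(fronts)
  d <- neckDepth(ser, center = c(0, 1e6), anchorX = seq(-375, 375, 15),
                 labels = seq(-250, 250, 10), referenceTime = 16)
  expect_equal(d$depth, c(0, 12, 24, 36), tolerance = 1e-6)
  still <- FrontSeries(lapply(16:19, function(t)
    FoldFront(cbind(seq(-400, 400, 10), 0), time = t)))
  d2 <- neckDepth(still, c(0, 1e6), seq(-300, 300, 20), referenceTime = 16)
  expect_true(all(d2$depth == 0))
  expect_error(neckDepth(ser, c(0, 1e6), 0, referenceTime = 40),
               class = "foldflow_config_error")
})

test_that("apex depth of a simulated arc follows the shrinking-circle law", {
  sched <- makeTensionSchedule("constant", list(T0 = 0.5))
  mu <- 8e-4                                 # c = T/mu = 625 um^2/h
  sim <- simulateFlow(openArc(300, 900), sched, mu, 16, 20,
                      frameTimes = seq(16, 20, 0.5))
  d <- neckDepth(sim, center = c(0, 300), anchorX = 0, labels = 0,
                 referenceTime = 16, labelRange = c(-1, 1))
  expected <- 300 - sqrt(300^2 - 2 * 625 * (d$time - 16))
  expect_equal(d$depth, expected, tolerance = 0.02)
})

test_that("tissue thickness is the apical-normal distance to the basal front", {
  ap <- FoldFront(cbind(seq(-100, 100, 5), 0), side = "apical")
  ba <- FoldFront(cbind(seq(-100, 100, 5), 10), side = "basal")
  th <- tissueThickness(ap, ba)
  expect_equal(th$thickness, rep(10, nrow(th)))
  th0 <- tissueThickness(ap, ap)
  expect_true(all(th0$thickness == 0))
  apc <- openArc(300, 600, 301)
  bac <- openArc(290, 580, 301, center = c(0, 300))
  thc <- tissueThickness(apc, bac, positions = c(100, 300, 500))
  expect_equal(thc$thickness, rep(10, 3), tolerance = 1e-3)
})
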