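test_that("zero tension leaves any simulated front unchanged", {
  f0 <- makeInitialFront("flattened_medial", 300, 100, 900, 61)
  sim <- simulateFlow(f0, makeTensionSchedule("constant", list(T0 = 0)),
                      mu = 1, 16, 20, frameTimes = c(16, 18, 20))
  p0 <- frontPoints(resampleFront(f0, 181))
  for (f in seriesFronts(sim))
    expect_equal(frontPoints(f), p0, tolerance = 1e-12)
})

test_that("a straight pinned front is stationary", {
  f0 <- FoldFront(cbind(seq(-100, 100, 5), 0))
  sim <- simulateFlow(f0, makeTensionSchedule("constant", list(T0 = 0.5)),
                      mu = 1e-3, 0, 5, frameTimes = c(0, 5),
                      config = flowConfig(nPoints = 41))
  expect_lt(max(abs(frontPoints(seriesFronts(sim)[[2]])[, 2])), 1e-9)
})

test_that("halving the step bound changes terminal fronts by a first-order margin", {
  f0 <- openArc(300, 900, n = 181)
  sched <- makeTensionSchedule("constant", list(T0 = 0.5))
  run <- function(dtMax) {
    sim <- simulateFlow(f0, sched, 8e-4, 16, 18, frameTimes = c(16, 18),
                        config = flowConfig(dtMax = dtMax))
    frontPoints(seriesFronts(sim)[[2]])
  }
  pA <- run(0.05); pB <- run(0.025); pC <- run(0.0125)
  dAB <- max(sqrt(rowSums((pA - pB)^2)))
  dBC <- max(sqrt(rowSums((pB - pC)^2)))
  expect_lt(dAB, 0.1)          # already step-bounded by the parabolic limit
  expect_lte(dBC, dAB + 1e-9)  # refining never increases the change
})

test_that("simulated flow is deterministic and hits requested frames", {
  f0 <- openArc(200, 500, 61)
  sched <- makeTensionSchedule("linear_ramp", list(T0 = 0.2, T1 = 0.6,
                                                   t0 = 14, t1 = 24))
  s1 <- simulateFlow(f0, sched, 4e-4, 16, 17, frameTimes = seq(16, 17, 0.25))
  s2 <- simulateFlow(f0, sched, 4e-4, 16, 17, frameTimes = seq(16, 17, 0.25))
  expect_identical(lapply(seriesFronts(s1), frontPoints),
                   lapply(seriesFronts(s2), frontPoints))
  expect_equal(seriesTimes(s1), seq(16, 17, 0.25))
})

test_that("the product error formula includes the cross term exactly", {
  expect_identical(productError(2, 0.1, 3, 0.2), 2 * 0.2 + 3 * 0.1 + 0.2 * 0.1)
  expect_identical(productError(5, 0, 7, 0), 0)
  expect_equal(productError(4, 0, 9, 0.3), 4 * 0.3)
  expect_error(productError(1, -0.1, 1, 0), class = "foldflow_config_error")
})

test_that("origin fits recover exact lines and flag constant-y data", {
  x <- 1:5
  f1 <- fitThroughOrigin(x, 2 * x)
  expect_equal(fitSlope(f1), 2)
  expect_equal(fitRSquared(f1), 1)
  expect_equal(fitSlopeSd(f1), 0, tolerance = 1e-12)
  f2 <- fitThroughOrigin(x, rep(3, 5))
  expect_equal(fitSlope(f2), 9 / 11)   # sum(xy)/sum(x^2) = 45/55
  expect_lte(fitRSquared(f2), 0)       # poor fit is flagged by R^2 <= 0
  f3 <- fitThroughOrigin(c(2, 2), c(3, 5))
  expect_equal(fitSlope(f3), 2)        # mean(y)/x
  expect_error(fitThroughOrigin(c(0, 0), c(1, 2)), class = "foldflow_data_error")
  # uncentered option
  f4 <- fitThroughOrigin(x, 2 * x, rSquared = "uncentered")
  expect_equal(fitRSquared(f4), 1)
})

test_that("collapse joins profile and tension and propagates the product error", {
  prof <- new("CurvatureSpeedProfile",
              data = data.frame(time = c(20, 20, 21), position_ml = c(0, 50, 0),
                                kappa = c(0, 0.002, 0.003),
                                kappa_sem = c(0, 1e-4, 1e-4),
                                speed = c(0, 1.5, 2.5),
                                speed_sem = c(0, 0.1, 0.1),
                                n_animals = c(6L, 6L, 6L)),
              removedFraction = 0)
  ten <- slidingAverageByDevTime(c(20, 21), c(0.3, 0.4), window = 0.5,
                                 evalTimes = c(20, 21))
  col <- buildCollapse(prof, ten)
  rec <- collapseRecords(col)
  expect_equal(rec$product, rec$kappa * rec$tension)
  expect_equal(rec$product[rec$kappa == 0], 0)
  expect_equal(rec$product[rec$position_ml == 50 & rec$time == 20], 6e-4)
  expect_equal(rec$product_sem,
               productError(rec$kappa, rec$kappa_sem, rec$tension, rec$tension_sd))
  # disjoint supports give an empty dataset with a warning
  tenFar <- slidingAverageByDevTime(30, 0.3, evalTimes = 30)
  expect_warning(colEmpty <- buildCollapse(prof, tenFar), "empty")
  expect_identical(nrow(collapseRecords(colEmpty)), 0L)
})

test_that("mu recovery inverts the slope, propagates its sd, and signals violations", {
  rec <- data.frame(time = 20, position_ml = seq(-50, 50, 25),
                    kappa = seq(1, 5) * 1e-3, kappa_sem = 0,
                    tension = 0.4, tension_sd = 0,
                    speed = seq(1, 5) * 1e-3 * 0.4 / 2e-4, speed_sem = 0)
  rec$product <- rec$kappa * rec$tension
  rec$product_sem <- 0
  col <- new("CollapseDataset", records = rec)
  out <- recoverMu(col)
  expect_equal(out$muHat, 2e-4, tolerance = 1e-12)
  expect_false(out$modelViolation)
  # common rescaling of both axes leaves mu unchanged
  rec10 <- rec
  rec10$product <- rec10$product * 10; rec10$kappa <- rec10$kappa * 10
  rec10$speed <- rec10$speed * 10
  out10 <- recoverMu(new("CollapseDataset", records = rec10))
  expect_equal(out10$muHat, out$muHat, tolerance = 1e-12)
  # zero speeds: slope 0 -> model violation signal, not an error
  recZ <- rec; recZ$speed <- 0
  expect_warning(outZ <- recoverMu(new("CollapseDataset", records = recZ)),
                 "model violation")
  expect_true(outZ$modelViolation)
  expect_true(is.na(outZ$muHat))
})

test_that("curvature CV is zero on circles and constant on static fronts", {
  rings <- FrontSeries(lapply(0:2, function(i) {
    f <- openArc(250 - 20 * i, 700 - 56 * i, 401, time = 16 + i, center = c(0, 250))
    f
  }))
  h <- homogeneityCV(rings, margin = 100)
  # interpolating triplets on the sampled polyline leaves sub-0.05% scatter
  expect_lt(max(h$cv), 5e-4)
  static <- FrontSeries(lapply(0:2, function(i) {
    f <- makeInitialFront("flattened_medial", 300, 100, 900, 301)
    f@time <- 16 + i
    f
  }))
  h2 <- homogeneityCV(static)
  expect_equal(h2$cv, rep(h2$cv[1], 3), tolerance = 1e-12)
  expect_gt(h2$cv[1], 0.3)
})
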