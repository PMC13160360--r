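test_that("water-mass rules reproduce the classification table", {
  expect_equal(as.character(classifyWaterMass(35.10, 2.5, 27.5)), "ATLANTIC")
  expect_equal(as.character(classifyWaterMass(35.10, 1.0, 27.8)),
               "MODIFIED_ATLANTIC")
  expect_equal(as.character(classifyWaterMass(34.70, 1.5, 27.5)), "WARM_POLAR")
  expect_equal(as.character(classifyWaterMass(34.50, -0.5, 27.50)), "POLAR")
  expect_equal(as.character(classifyWaterMass(34.90, -1.3, 28.05)), "CBSDW")
  expect_equal(as.character(classifyWaterMass(34.90, -0.5, 28.05)),
               "INTERMEDIATE")
  # boundary: exactly 0 deg C goes to the cold branch, 35.06 is Atlantic-side
  expect_equal(as.character(classifyWaterMass(35.06, 2.5, 27.5)), "ATLANTIC")
  expect_equal(as.character(classifyWaterMass(34.9, 0, 27.97)), "POLAR")
  expect_error(classifyWaterMass(NA, 1, 27), "finite")
})

test_that("water-mass classification is total and matches the rule-table oracle", {
  set.seed(42)
  n <- 20000
  SA <- runif(n, 33.5, 35.6)
  CT <- runif(n, -2, 8)
  ST <- runif(n, 26.5, 28.6)
  got <- as.character(classifyWaterMass(SA, CT, ST))
  expect_false(any(got == "UNCLASSIFIED")) # total on physical inputs
  expect_identical(got, unname(waterMassOracle(SA, CT, ST)))
})

test_that("calibration offsets recover a constructed sensor shift", {
  ref <- rampProfile(n = 60)
  shifted <- ctdProfile("p2", ref@depth, ref@CT - 0.1, ref@SA, latitude = 77)
  off <- calibrateOffsets(ref, shifted, window = c(20, 40))
  expect_equal(unname(off["dT"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(off["dS"]), 0, tolerance = 1e-12)
  # identity: zero offsets
  expect_equal(unname(calibrateOffsets(ref, ref, c(20, 40))), c(0, 0))
  # applying the offsets reproduces the reference within machine tolerance
  fixed <- applyOffsets(shifted, off)
  expect_equal(fixed@CT, ref@CT, tolerance = 1e-12)
  # gradient guard refuses an unstable window
  steep <- rampProfile(n = 60, dTdz = 0.5)
  expect_error(calibrateOffsets(steep, steep, c(20, 40)), "unstable")
  expect_error(calibrateOffsets(ref, ref, c(100, 120)), "outside")
})

test_that("noisy calibration recovers the planted shift within 3 SEM", {
  nRep <- 30; n <- 80; sdNoise <- 0.05
  sem <- sdNoise * sqrt(2) / sqrt(50) # both profiles noisy, 50-sample window
  hits <- vapply(seq_len(nRep), function(k) {
    set.seed(900 + k)
    depth <- 0:(n - 1)
    ref <- ctdProfile("r", depth, 2 + rnorm(n, sd = sdNoise), rep(35, n),
                      latitude = 77)
    tgt <- ctdProfile("t", depth, 2 - 0.1 + rnorm(n, sd = sdNoise),
                      rep(35, n), latitude = 77)
    off <- calibrateOffsets(ref, tgt, c(10, 59), maxGradient = 1)
    abs(off[["dT"]] - 0.1) <= 3 * sem
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Brunt-Vaisala frequency follows the closed form and sign convention", {
  # uniform density -> zero stratification
  flat <- ctdProfile("f", 0:20, rep(1, 21), rep(35, 21),
                     sigmaTheta = rep(27.5, 21))
  expect_true(all(bruntVaisala(flat)$n2 == 0))
  # linear increase at 0.01 kg m-3 per m -> N2 = g * 0.01 / rho0 everywhere
  lin <- ctdProfile("l", 0:20, rep(1, 21), rep(35, 21),
                    sigmaTheta = 27 + 0.01 * (0:20))
  expect_equal(bruntVaisala(lin, g = 9.81, rho0 = 1025)$n2,
               rep(9.81 * 0.01 / 1025, 20), tolerance = 1e-10)
  # inverted profile -> negative N2
  inv <- ctdProfile("i", 0:20, rep(1, 21), rep(35, 21),
                    sigmaTheta = 28 - 0.01 * (0:20))
  expect_true(all(bruntVaisala(inv)$n2 < 0))
  # monotone-increasing density -> non-negative everywhere (property)
  set.seed(5)
  for (k in 1:20) {
    st <- cumsum(c(27, runif(30, 0, 0.05)))
    p <- ctdProfile("m", 0:30, rep(0, 31), rep(35, 31), sigmaTheta = st)
    expect_true(all(bruntVaisala(p)$n2 >= 0))
  }
  expect_error(bruntVaisala(ctdProfile("d", 0, 1, 35)), "two depth levels")
})

test_that("section interpolation is exact at profiles, linear between, masked outside", {
  p1 <- rampProfile("a", lat = 76.0, n = 51, t0 = 4)
  p2 <- rampProfile("b", lat = 77.0, n = 51, t0 = 0)
  sec <- interpolateSection(list(p2, p1), latGrid = c(76.0, 76.5, 77.0),
                            depthGrid = seq(0, 50, 5))
  expect_equal(sec@CT[1, ], rep(4, 11))        # identity at a profile
  expect_equal(sec@CT[3, ], rep(0, 11))
  expect_equal(sec@CT[2, ], rep(2, 11))        # arithmetic mean midway
  # hull rule: below the shallower profile everything is masked
  shallow <- rampProfile("c", lat = 76.5, n = 21, t0 = 2)
  sec2 <- interpolateSection(list(p1, shallow), latGrid = c(76.0, 76.2, 76.5),
                             depthGrid = seq(0, 50, 5))
  expect_true(all(sec2@mask[2, 6:11]))         # 25-50 m between stations
  expect_true(all(!sec2@mask[2, 1:5]))
  expect_error(interpolateSection(list(p1)), "two profiles")
})

test_that("subsurface front sits at the maximum band-mean temperature gradient", {
  # step between grid nodes -> midpoint of the steepest interval, grid-snapped
  lats <- seq(76.005, 77.005, by = 0.01)
  mkSec <- function(tvals) {
    z <- seq(40, 60, 5)
    new("CtdSection", latitude = lats, depth = z,
        CT = matrix(tvals, length(lats), length(z)),
        SA = matrix(35, length(lats), length(z)),
        sigmaTheta = matrix(27.5, length(lats), length(z)),
        mask = matrix(FALSE, length(lats), length(z)))
  }
  stepT <- ifelse(lats < 76.50, 4, 0) # jump between the 76.495 / 76.505 nodes
  got <- locateSubsurfaceFront(mkSec(stepT), band = c(45, 55))
  expect_equal(got, 76.50, tolerance = 1e-9)
  # spatially constant temperature -> no front
  expect_true(is.na(locateSubsurfaceFront(mkSec(rep(2, length(lats))))))
  # band fully outside the section errors
  expect_error(locateSubsurfaceFront(mkSec(stepT), band = c(100, 110)),
               "depth band")
})

test_that("planted logistic fronts are recovered to grid resolution", {
  # transition widths across the estimator's validity regime (<= 0.05 deg)
  errs <- vapply(1:25, function(k) {
    set.seed(300 + k)
    latF <- runif(1, 76.95, 77.45)
    w <- runif(1, 0.02, 0.05)
    sc <- simulationConfig(seed = 300 + k, front = list(lat = latF, width = w))
    out <- simulateCtdTransect(sc)
    abs(locateSubsurfaceFront(out$section) - latF)
  }, numeric(1))
  expect_gte(mean(errs <= 0.0100001), 0.96)
  expect_lte(stats::median(errs), 0.01)
})

test_that("width -> 0 produces a sharp temperature jump across the front", {
  sc <- simulationConfig(seed = 2, front = list(width = 0),
                         noise = list(svJitter = 0))
  out <- simulateCtdTransect(sc, latGrid = c(77.19, 77.1999, 77.2001, 77.21),
                             depthGrid = c(100, 110))
  jump <- out$section@CT[2, 1] - out$section@CT[3, 1]
  expect_equal(jump, 3.2 - (-1.8), tolerance = 0.05) # sensor noise only
})

test_that("surface front locator handles step, constant and absent cases", {
  lat <- seq(76, 78, by = 0.05)
  sstStep <- ifelse(lat < 77.12, 3, -1) # jump between the 77.10 / 77.15 samples
  got <- locateSurfaceFront(lat, sstStep)
  expect_gte(got, 77.10); expect_lte(got, 77.15)
  expect_true(is.na(locateSurfaceFront(lat, rep(5, length(lat)))))
  # weak gradual gradient below the minimum -> absent (summer situation)
  expect_true(is.na(locateSurfaceFront(lat, 6 - 0.2 * (lat - 76),
                                       minGradient = 0.5)))
  expect_error(locateSurfaceFront(rev(lat), sstStep), "increasing")
  expect_error(locateSurfaceFront(lat[1:2], sstStep[1:2]), "three points")
})

test_that("distance to a frontal feature is signed haversine at 6371 km radius", {
  expect_equal(distanceToFeature(77.2, 29.5, 77.2), 0)
  oneDeg <- 6371 * pi / 180
  expect_equal(distanceToFeature(78.2, 29.5, 77.2), oneDeg, tolerance = 1e-4)
  north <- distanceToFeature(77.7, 29.5, 77.2)
  south <- distanceToFeature(76.7, 29.5, 77.2)
  expect_equal(north, -south, tolerance = 1e-9)
  expect_gt(north, 0)
  expect_equal(distanceToFeature(77.7, 29.5, 77.2, signed = FALSE),
               abs(north))
  expect_error(distanceToFeature(95, 0, 77), "latitude")
})
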