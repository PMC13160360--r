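test_that("sound-speed/absorption re-correction matches the closed forms", {
  g <- flatGrid(np = 5, nb = 200, sv = -70)
  # identity
  same <- recorrectSv(g, 1480, 1480, 0.01, 0.01)
  expect_equal(sv(same), sv(g))
  expect_equal(depthEdges(same), depthEdges(g))
  # doubling c at zero absorption adds 20 log10(2) everywhere
  dbl <- recorrectSv(flatGrid(np = 2, nb = 200, sv = -70, alpha = 0),
                     1480, 2960, 0, 0)
  expect_equal(sv(dbl) - (-70),
               matrix(20 * log10(2), 2, 200), tolerance = 1e-10)
  expect_equal(depthEdges(dbl), (0:200) * 2)
  # absorption change of 0.001 dB/m at r = 100 m (bin 99.5-100.5) -> +0.2 dB
  da <- recorrectSv(flatGrid(np = 2, nb = 200, sv = -70, alpha = 0.001),
                    1480, 1480, 0.001, 0.002)
  expect_equal(sv(da)[1, 101] - (-70), 2 * 0.001 * 100.5, tolerance = 1e-10)
  expect_error(recorrectSv(g, 0, 1480, 0, 0), "positive")
})

test_that("absorption coefficient matches an independent evaluation and limits", {
  # independent term-by-term oracle, 4 significant figures
  for (f in c(18, 38, 120)) {
    got <- absorptionCoefficient(f, T = 4, S = 35, z = 100, pH = 8)
    expect_equal(got, fgOracle(f, 4, 35, 100, 8), tolerance = 1e-4)
  }
  # strictly increasing with frequency at fixed conditions
  a <- absorptionCoefficient(c(18, 38, 120), T = 1, S = 34.8, z = 100)
  expect_true(all(diff(a) > 0))
  # freshwater limit collapses to the pure-water term
  fw <- absorptionCoefficient(38, T = 10, S = 0, z = 0, pH = 8)
  A3 <- 4.937e-4 - 2.59e-5 * 10 + 9.11e-7 * 100 - 1.50e-8 * 1000
  expect_equal(fw, A3 * 38^2 / 1000, tolerance = 1e-6)
  expect_error(absorptionCoefficient(5), "10-500")
})

test_that("near-field exclusion depth follows pi a^2 / lambda + buffer", {
  g <- flatGrid(np = 4, nb = 30, freq = 38)
  ex <- excludeSurface(g, a = 0.2, soundSpeed = 1480, buffer = 2)
  lambda <- 1480 / 38000
  want <- pi * 0.2^2 / lambda + 2 # = 5.23 m for these values
  expect_equal(surfaceLine(ex), rep(want, 4), tolerance = 1e-9)
  expect_equal(round(want, 2), 5.23)
  # bins whose top edge is above the line are masked (half-open bins)
  expect_true(all(maskLayer(ex, "surface")[, 1:6]))
  expect_false(any(maskLayer(ex, "surface")[, 7:30]))
  # a -> 0, buffer 0: exclusion depth collapses to zero
  ex0 <- excludeSurface(g, a = 1e-6, buffer = 0)
  expect_lt(surfaceLine(ex0)[1], 1e-9)
  expect_false(any(maskLayer(ex0, "surface")[, -1]))
  # per-ping override deepens the line
  exo <- excludeSurface(g, a = 0.2, buffer = 2,
                        override = c(10, NA, NA, NA))
  expect_true(all(maskLayer(exo, "surface")[1, 1:10]))
  expect_error(excludeSurface(g, a = 0), "positive")
})

test_that("bottom detection masks the dead zone above a planted seabed", {
  g <- flatGrid(np = 3, nb = 220, sv = -70)
  s <- sv(g); s[, 201:220] <- -20 # seabed echo from 200 m
  g@Sv <- s
  ex <- detectAndExcludeBottom(g, threshold = -35, minDepth = 20)
  expect_equal(bottomLine(ex), rep(200, 3))
  m <- maskLayer(ex, "bottom")
  # bin [198,199) contains 198.5 m -> masked; [197,198) is not
  expect_true(all(m[, 199:220]))
  expect_false(any(m[, 1:198]))
  # no echo above threshold -> no bottom, no masking
  none <- detectAndExcludeBottom(flatGrid(np = 3, nb = 220, sv = -70))
  expect_true(all(is.na(bottomLine(none))))
  expect_false(any(maskLayer(none, "bottom")))
  # manual override wins over the detector
  ovr <- detectAndExcludeBottom(g, override = c(150, NA, NA))
  expect_equal(bottomLine(ovr)[1], 150)
  expect_true(all(maskLayer(ovr, "bottom")[1, 150:220]))
})

test_that("background-noise removal recovers a planted noise floor exactly", {
  # deterministic TVG-amplified noise field, no signal
  nb <- 200; np <- 80; N0 <- -125; alpha <- 0.01
  r <- (1:nb) - 0.5
  svNoise <- N0 + 20 * log10(r) + 2 * alpha * r
  g <- echogramGrid(38, matrix(rep(svNoise, each = np), np), 0:nb,
                    absorption = alpha)
  out <- removeBackgroundNoise(g, cell = c(20L, 10L))
  expect_equal(out$noise@noise, rep(N0, 4), tolerance = 1e-9)
  # pure noise: everything fails the 10 dB SNR rule
  expect_gte(mean(maskLayer(out$grid, "noise")), 0.99)
  # planted signal 30 dB above the noise at its depth: additive model is
  # inverted exactly, so the corrected Sv equals the planted signal
  sig <- -60
  g2 <- g
  g2@Sv[, 96:105] <- .lin2 <- 10 * log10(10^(sig / 10) +
                                         10^(rep(svNoise[96:105], each = np) / 10))
  out2 <- removeBackgroundNoise(g2, cell = c(20L, 10L))
  expect_equal(out2$grid@Sv[, 96:105], matrix(sig, np, 10), tolerance = 0.01)
  expect_false(any(maskLayer(out2$grid, "noise")[, 96:105]))
  # negligible noise floor -> output equals input on unmasked samples
  g3 <- flatGrid(np = 40, nb = 40, sv = -70, alpha = 0)
  out3 <- removeBackgroundNoise(g3, cell = c(20L, 10L), maxNoise = -200)
  keep <- !maskLayer(out3$grid, "noise")
  expect_equal(out3$grid@Sv[keep], rep(-70, sum(keep)), tolerance = 1e-6)
  expect_error(removeBackgroundNoise(flatGrid(5, 5), cell = c(50L, 10L)),
               "larger than the grid")
})

test_that("impulse removal flags isolated pings and restores the background", {
  g <- flatGrid(np = 21, nb = 30, sv = -70)
  g@Sv[11, ] <- -50 # single elevated ping, +20 dB
  out <- removeImpulseNoise(g, context = 1, smoothWindow = 3)
  flg <- maskLayer(out, "impulse_repaired")
  expect_true(all(flg[11, ]))
  expect_equal(sum(flg), 30) # nothing else flagged
  expect_equal(out@Sv[11, ], rep(-70, 30), tolerance = 0.1)
  # flat field -> zero flags
  flat <- removeImpulseNoise(flatGrid(np = 21, nb = 30), context = 1,
                             smoothWindow = 3)
  expect_equal(sum(maskLayer(flat, "impulse_repaired")), 0)
  # edge ping: one-sided comparison still flags
  ge <- flatGrid(np = 21, nb = 30, sv = -70)
  ge@Sv[1, ] <- -50
  oute <- removeImpulseNoise(ge, context = 1, smoothWindow = 3)
  expect_true(all(maskLayer(oute, "impulse_repaired")[1, ]))
  expect_error(removeImpulseNoise(flatGrid(np = 3, nb = 5), context = 5),
               "context")
})

test_that("adjacent contaminated pings evade the two-sided rule at context 1", {
  # brute-force oracle over the flag rule on a tiny grid
  g <- flatGrid(np = 15, nb = 4, sv = -70)
  g@Sv[7:8, ] <- -50
  out <- removeImpulseNoise(g, context = 1, smoothWindow = 1, threshold = 10)
  flg <- maskLayer(out, "impulse_repaired")
  # oracle: flag iff both ping-distance-1 neighbours are > 10 dB lower
  oracle <- matrix(FALSE, 15, 4)
  for (p in 1:15) for (d in 1:4) {
    lhs <- if (p > 1) g@Sv[p, d] - g@Sv[p - 1, d] > 10 else NA
    rhs <- if (p < 15) g@Sv[p, d] - g@Sv[p + 1, d] > 10 else NA
    oracle[p, d] <- if (is.na(lhs)) isTRUE(rhs) else if (is.na(rhs)) isTRUE(lhs)
                    else isTRUE(lhs) && isTRUE(rhs)
  }
  expect_equal(unname(flg), oracle)
  expect_false(any(flg[7:8, ])) # interior pair shields itself
})

test_that("resampling aligns clocks and depth bins to the reference", {
  mk <- function(freq, offset, np = 10, nb = 20, sv = -70)
    echogramGrid(freq, matrix(sv, np, nb), 0:nb,
                 pingTime = (seq_len(np) - 1) + offset)
  # identical clocks -> identity
  out <- resampleToReference(list(f38 = mk(38, 0), f120 = mk(120, 0)))
  expect_equal(sv(out$f120), sv(out$f38))
  expect_false(any(exclusionMask(out$f120)[, 2:19]))
  # +0.4 s offset within tolerance: one-to-one nearest matching
  out2 <- resampleToReference(list(f38 = mk(38, 0), f18 = mk(18, 0.4)))
  expect_equal(sv(out2$f18)[, 10], rep(-70, 10))
  # a gap larger than the tolerance masks whole columns
  gappy <- mk(120, 0)
  gappy@pingTime[5] <- 100
  out3 <- resampleToReference(list(f38 = mk(38, 0), f120 = gappy),
                              tolerance = 0.5)
  expect_true(all(maskLayer(out3$f120, "resample")[5, ]))
  expect_false(any(maskLayer(out3$f120, "resample")[4, ]))
  late <- mk(120, 1e6)
  expect_error(resampleToReference(list(f38 = mk(38, 0), f120 = late)),
               "overlap")
})

test_that("linear-domain smoothing honours the closed form and the mask", {
  # constant field unchanged
  g <- flatGrid(np = 11, nb = 11, sv = -66, stage = "raw")
  sm <- smoothSv(g)
  expect_equal(sv(sm), sv(g), tolerance = 1e-10)
  # single -60 dB sample in a -Inf background: 10 log10(10^-6 / 25)
  g2 <- flatGrid(np = 11, nb = 11, sv = -Inf)
  g2@Sv[6, 6] <- -60
  sm2 <- smoothSv(g2)
  expect_equal(sm2@Sv[6, 6], 10 * log10(1e-6 / 25), tolerance = 1e-9)
  # masked neighbours are excluded from the denominator
  g3 <- flatGrid(np = 11, nb = 11, sv = -60)
  m <- matrix(FALSE, 11, 11); m[6, 7] <- TRUE
  g3@masks$surface <- m
  g3@Sv[6, 7] <- 0 # junk under the mask must not leak into any mean
  sm3 <- smoothSv(g3)
  expect_equal(sm3@Sv[6, 6], -60, tolerance = 1e-9)
  # dB-domain averaging would give a different (wrong) answer
  dbMean <- mean(c(rep(-70, 24), -50))
  linMean <- 10 * log10(mean(10^(c(rep(-70, 24), -50) / 10)))
  expect_gt(abs(dbMean - linMean), 1)
  g4 <- flatGrid(np = 11, nb = 11, sv = -70)
  g4@Sv[6, 6] <- -50
  sm4 <- smoothSv(g4)
  expect_equal(sm4@Sv[6, 6], linMean, tolerance = 1e-9)
  expect_error(smoothSv(flatGrid(5, 5), window = c(4, 5)), "odd")
})

test_that("the minimum-Sv threshold keeps the boundary and matches brute force", {
  set.seed(11)
  vals <- round(runif(600, -95, -60), 3)
  vals[1:5] <- -80 # exact boundary values retained (strict <)
  g <- echogramGrid(38, matrix(vals, 20, 30), 0:30, stage = "smoothed")
  th <- applySvThreshold(g, -80)
  expect_false(any(maskLayer(th, "below_threshold")[1:5, 1]))
  expect_equal(sum(!maskLayer(th, "below_threshold")), sum(vals >= -80))
  allLow <- applySvThreshold(flatGrid(5, 6, sv = -90, stage = "smoothed"))
  expect_true(all(maskLayer(allLow, "below_threshold")))
})

test_that("MVBS cells average in the linear domain and honour the mask", {
  g <- flatGrid(np = 10, nb = 12, sv = -70)
  g@distance <- (0:9) * 0.1
  mv <- computeMvbs(g, cellDepth = 3, cellDist = 0.25)
  expect_true(all(abs(mvbs(mv) - -70) < 1e-9))
  # half -60, half -70 in one cell
  g2 <- flatGrid(np = 4, nb = 2, sv = -70)
  g2@Sv[1:2, ] <- -60
  g2@distance <- c(0, 0.05, 0.1, 0.15)
  mv2 <- computeMvbs(g2, cellDepth = 2, cellDist = 1)
  expect_equal(mvbs(mv2)[1, 1], 10 * log10((1e-6 + 1e-7) / 2),
               tolerance = 1e-9)
  # fully masked cell stays undefined, never 0
  g3 <- flatGrid(np = 4, nb = 4, sv = -70)
  g3@masks$surface <- matrix(TRUE, 4, 4)
  mv3 <- computeMvbs(g3, cellDepth = 4, cellDist = 1)
  expect_true(all(is.na(mvbs(mv3))))
  expect_equal(mv3@validFraction[1, 1], 0)
  expect_error(computeMvbs(g, cellDepth = 0), "positive")
})

test_that("the cleaning chain enforces its stage order and monotone masks", {
  sc <- simulationConfig(seed = 5, transect = list(nPings = 60L,
                                                   maxDepth = 120),
                         targets = list(), seabed = 110)
  g <- simulateEchograms(sc)$grids$f38
  g1 <- excludeSurface(g)
  g2 <- detectAndExcludeBottom(g1)
  g3 <- removeBackgroundNoise(g2, cell = c(20L, 10L))$grid
  # reordering is a contract error
  expect_error(excludeSurface(g3), "pipeline order")
  expect_error(resampleToReference(list(g3)), "pipeline order")
  g4 <- removeImpulseNoise(g3, context = 1, smoothWindow = 3)
  g5 <- smoothSv(g4)
  expect_error(removeBackgroundNoise(g5), "pipeline order")
  g6 <- applySvThreshold(g5)
  expect_error(smoothSv(g6), "pipeline order")
  expect_error(recorrectSv(g6, 1480, 1490, 0.01, 0.01), "pipeline order")
  # masks are monotone through the chain
  stages <- list(g1, g2, g3, g4, g5, g6)
  for (k in 2:length(stages)) {
    prev <- exclusionMask(stages[[k - 1]])
    expect_false(any(prev & !exclusionMask(stages[[k]])))
  }
})

test_that("echogram CSV round-trip preserves values, masks and lines exactly", {
  sc <- simulationConfig(seed = 9, transect = list(nPings = 40L,
                                                   maxDepth = 60))
  g <- simulateEchograms(sc)$grids$f120
  g <- excludeSurface(g)
  path <- tempfile(fileext = ".csv")
  writeEchogramCsv(g, path)
  back <- readEchogramCsv(path)
  expect_identical(sv(back), sv(g))
  expect_identical(back@masks, g@masks)
  expect_identical(back@lines$surface, g@lines$surface)
  expect_identical(back@depthEdges, g@depthEdges)
  expect_identical(back@pingTime, g@pingTime)
  expect_identical(back@stage, g@stage)
  unlink(path)
})
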