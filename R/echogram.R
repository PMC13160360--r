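## The echogram cleaning chain: from raw Sv grids to thresholded, smoothed,
## gridded MVBS per frequency. Operations must be applied in chain order
## (resample, exclusions, background noise, impulse noise, smoothing,
## threshold); see .advanceStage().

#' Re-correct Sv for in-situ sound speed and absorption
#'
#' Echosounders log Sv using nominal sound speed and absorption; with CTD
#' measurements available the ranges and TVG terms are re-corrected:
#' r' = r * (c'/c), Sv' = Sv + 20 log10(r'/r) + 2 (a' r' - a r), and the
#' depth-bin edges rescale with the ranges. Rows at zero range are masked
#' rather than corrected.
#'
#' @param grid a raw \linkS4class{EchogramGrid}.
#' @param cOld,cNew old and new sound speed, m s-1 (positive).
#' @param alphaOld,alphaNew old and new absorption, dB m-1 (>= 0).
#' @return the corrected grid (still stage "raw": correction precedes the
#'   cleaning chain).
#' @export
recorrectSv <- function(grid, cOld, cNew, alphaOld, alphaNew) {
  if (cOld <= 0 || cNew <= 0) stop("sound speeds must be positive")
  if (alphaOld < 0 || alphaNew < 0) stop("absorption must be non-negative")
  if (.stageRank[grid@stage] > 0)
    stop("pipeline order violation: recorrectSv applies to raw grids only",
         call. = FALSE)
  rOld <- .binCenters(grid@depthEdges)
  ratio <- cNew / cOld
  rNew <- rOld * ratio
  zero <- rOld == 0
  dSv <- 20 * log10(ratio) + 2 * (alphaNew * rNew - alphaOld * rOld)
  dSv[zero] <- 0
  grid@Sv <- sweep(grid@Sv, 2, dSv, `+`)
  if (any(zero)) {
    m <- matrix(FALSE, nrow(grid@Sv), ncol(grid@Sv)); m[, zero] <- TRUE
    grid <- .addMask(grid, "invalid_range", m)
  }
  grid@depthEdges <- grid@depthEdges * ratio
  grid@soundSpeed <- cNew
  grid@absorption <- alphaNew
  grid
}

#' Seawater absorption coefficient (Francois-Garrison)
#'
#' Sum of the boric-acid, magnesium-sulfate and pure-water viscosity
#' contributions of the Francois & Garrison formulation, valid for
#' frequencies of roughly 10-500 kHz.
#'
#' @param f frequency, kHz (vectorized).
#' @param T temperature, deg C.
#' @param S salinity, psu.
#' @param z depth, m.
#' @param pH seawater pH (default 8).
#' @return absorption coefficient alpha, dB m-1.
#' @export
absorptionCoefficient <- function(f, T = 4, S = 35, z = 100, pH = 8) {
  if (any(f < 10 | f > 500)) stop("frequency outside the 10-500 kHz range")
  th <- 273 + T
  c <- 1412 + 3.21 * T + 1.19 * S + 0.0167 * z
  ## boric acid
  A1 <- 8.86 / c * 10^(0.78 * pH - 5)
  f1 <- 2.8 * sqrt(S / 35) * 10^(4 - 1245 / th)
  P1 <- 1
  ## magnesium sulfate
  A2 <- 21.44 * S / c * (1 + 0.025 * T)
  f2 <- 8.17 * 10^(8 - 1990 / th) / (1 + 0.0018 * (S - 35))
  P2 <- 1 - 1.37e-4 * z + 6.2e-9 * z^2
  ## pure water
  P3 <- 1 - 3.83e-5 * z + 4.9e-10 * z^2
  A3 <- ifelse(T <= 20,
               4.937e-4 - 2.59e-5 * T + 9.11e-7 * T^2 - 1.50e-8 * T^3,
               3.964e-4 - 1.146e-5 * T + 1.45e-7 * T^2 - 6.5e-10 * T^3)
  dBkm <- A1 * P1 * f1 * f^2 / (f1^2 + f^2) +
    A2 * P2 * f2 * f^2 / (f2^2 + f^2) + A3 * P3 * f^2
  dBkm / 1000
}

#' Exclude the transducer near field and surface noise
#'
#' Masks all samples above the near-field (Fresnel-zone) range plus a
#' buffer. The on-axis near-field range of a circular transducer of active
#' radius a is pi a^2 / lambda with lambda = c / f; the exclusion line is
#' lowered a further \code{buffer} metres (default 2 m) to clear residual
#' surface noise. A per-ping manual override supports deepening the line
#' under bubble sweep-down or ice.
#'
#' @param grid an \linkS4class{EchogramGrid}.
#' @param a transducer active radius, m (> 0).
#' @param soundSpeed sound speed, m s-1; defaults to the grid's.
#' @param buffer extra exclusion below the near field, m (default 2).
#' @param override optional per-ping exclusion depth, m (NA = automatic).
#' @return grid with mask layer "surface" and line "surface" set.
#' @export
excludeSurface <- function(grid, a = 0.2, soundSpeed = NULL, buffer = 2,
                           override = NULL) {
  if (a <= 0) stop("transducer radius must be positive")
  if (is.null(soundSpeed)) soundSpeed <- grid@soundSpeed
  lambda <- soundSpeed / (grid@frequency * 1000)
  excl <- pi * a^2 / lambda + buffer
  line <- rep(excl, nrow(grid@Sv))
  if (!is.null(override)) {
    stopifnot(length(override) == nrow(grid@Sv))
    line[!is.na(override)] <- override[!is.na(override)]
  }
  tops <- grid@depthEdges[-length(grid@depthEdges)]
  m <- outer(line, tops, function(l, t) t < l)
  whole <- line > max(grid@depthEdges)
  if (any(whole))
    warning(sprintf("surface exclusion deeper than the water column for %d ping(s); whole ping(s) masked",
                    sum(whole)))
  grid <- .addMask(grid, "surface", m)
  grid@lines$surface <- line
  ## exclusions may follow resampling or raw grids, but not later stages
  if (.stageRank[grid@stage] > .stageRank["excluded"])
    stop("pipeline order violation: surface exclusion must precede noise removal",
         call. = FALSE)
  grid@stage <- "excluded"
  grid
}

#' Detect the seabed and exclude the bottom dead zone
#'
#' Per ping, the bottom is the shallowest sample below \code{minDepth}
#' whose Sv reaches \code{threshold}; everything from \code{offset} metres
#' (default 1.5 m) above that line downward is masked to exclude the
#' bottom dead zone. Pings without a detection keep their full column
#' (absence of a bottom echo is valid in deep water). A per-ping manual
#' override replaces erroneous detections.
#'
#' @param grid an \linkS4class{EchogramGrid}.
#' @param threshold bottom-echo detection threshold, dB (default -35).
#' @param minDepth shallowest admissible bottom, m; must sit below the
#'   surface exclusion.
#' @param offset dead-zone clearance above the bottom, m (default 1.5).
#' @param override optional per-ping bottom depth, m (NA = automatic).
#' @return grid with mask layer "bottom" and line "bottom" (NA where no
#'   bottom was found) set.
#' @export
detectAndExcludeBottom <- function(grid, threshold = -35, minDepth = 20,
                                   offset = 1.5, override = NULL) {
  sl <- grid@lines$surface
  if (!is.null(sl) && any(minDepth < sl))
    stop("minDepth must lie below the surface exclusion line")
  tops <- grid@depthEdges[-length(grid@depthEdges)]
  bottoms <- grid@depthEdges[-1]
  cand <- tops >= minDepth
  line <- rep(NA_real_, nrow(grid@Sv))
  for (p in seq_len(nrow(grid@Sv))) {
    hit <- which(cand & grid@Sv[p, ] >= threshold)
    if (length(hit)) line[p] <- tops[hit[1]]
  }
  if (!is.null(override)) {
    stopifnot(length(override) == nrow(grid@Sv))
    line[!is.na(override)] <- override[!is.na(override)]
  }
  m <- matrix(FALSE, nrow(grid@Sv), ncol(grid@Sv))
  det <- which(!is.na(line))
  for (p in det) m[p, ] <- bottoms > line[p] - offset
  grid <- .addMask(grid, "bottom", m)
  grid@lines$bottom <- line
  if (.stageRank[grid@stage] < .stageRank["excluded"])
    grid@stage <- "excluded"
  else if (.stageRank[grid@stage] > .stageRank["excluded"])
    stop("pipeline order violation: bottom exclusion must precede noise removal",
         call. = FALSE)
  grid
}

#' Background-noise removal with SNR thresholding
#'
#' Estimates the background-noise level from the data and subtracts it in
#' the linear domain. TVG-removed power P = Sv - 20 log10 r - 2 a r is
#' averaged (linear domain) over cells of \code{cell[1]} pings x
#' \code{cell[2]} samples; the noise level of each ping block is the
#' minimum cell mean over depth, capped at \code{maxNoise}. The noise is
#' re-amplified to Sv_noise(r) = noise + 20 log10 r + 2 a r, subtracted
#' linearly, and samples whose corrected SNR (Sv_corr - Sv_noise) falls
#' below \code{snrThreshold} (default 10 dB), or whose linear difference
#' is non-positive, are masked.
#'
#' @param grid an \linkS4class{EchogramGrid} (absorption and sound speed
#'   taken from the grid).
#' @param cell integration cell c(pings, samples) (default c(40, 10)).
#' @param snrThreshold minimum retained SNR, dB (default 10).
#' @param maxNoise cap on the noise estimate, dB (default -100): guards
#'   against biologically saturated blocks inflating the estimate.
#' @return list with elements \code{grid} (noise-subtracted, mask layer
#'   "noise" added) and \code{noise} (a \linkS4class{NoiseEstimate}).
#' @export
removeBackgroundNoise <- function(grid, cell = c(40L, 10L), snrThreshold = 10,
                                  maxNoise = -100) {
  np <- nrow(grid@Sv); nb <- ncol(grid@Sv)
  if (cell[1] > np || cell[2] > nb)
    stop("noise-estimation cell larger than the grid")
  grid <- .advanceStage(grid, "noise_removed")
  r <- .binCenters(grid@depthEdges)
  tvg <- 20 * log10(pmax(r, .Machine$double.eps)) + 2 * grid@absorption * r
  excl <- exclusionMask(grid)
  P <- sweep(grid@Sv, 2, tvg, `-`)
  Plin <- .dbToLin(P); Plin[excl] <- NA
  pingBlock <- (seq_len(np) - 1L) %/% cell[1] + 1L
  sampBlock <- (seq_len(nb) - 1L) %/% cell[2] + 1L
  nPB <- max(pingBlock)
  noise <- rep(NA_real_, nPB)
  for (b in seq_len(nPB)) {
    rows <- which(pingBlock == b)
    means <- tapply(colMeans(Plin[rows, , drop = FALSE], na.rm = TRUE),
                    sampBlock, mean, na.rm = TRUE)
    means <- means[is.finite(means)]
    noise[b] <- if (length(means)) min(.linToDb(min(means)), maxNoise) else maxNoise
  }
  svNoise <- outer(noise[pingBlock] * 0, tvg, `+`) + noise[pingBlock]
  linDiff <- .dbToLin(grid@Sv) - .dbToLin(svNoise)
  pos <- linDiff > 0
  svCorr <- grid@Sv
  svCorr[pos] <- .linToDb(linDiff[pos])
  bad <- !pos | (svCorr - svNoise) < snrThreshold
  grid@Sv <- svCorr
  grid <- .addMask(grid, "noise", bad)
  est <- new("NoiseEstimate", frequency = grid@frequency, noise = noise,
             blockStart = as.integer((seq_len(nPB) - 1L) * cell[1] + 1L),
             cell = as.integer(cell), snrThreshold = snrThreshold,
             maxNoise = maxNoise)
  list(grid = grid, noise = est)
}

## running mean over the sample (depth) dimension, linear domain, per ping
.verticalSmooth <- function(Sv, k) {
  if (k <= 1) return(Sv)
  lin <- .dbToLin(Sv)
  half <- (k - 1) %/% 2
  nb <- ncol(lin)
  cs <- cbind(0, t(apply(lin, 1, cumsum)))
  lo <- pmax(seq_len(nb) - half, 1); hi <- pmin(seq_len(nb) + half, nb)
  out <- (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(lin))
  .linToDb(out)
}

#' Impulse-noise removal by two-sided ping comparison
#'
#' Detects isolated high-intensity pings (electrical interference from
#' other instruments). After vertical smoothing over \code{smoothWindow}
#' samples, a sample is flagged as impulse noise when it exceeds both the
#' sample at the same depth \code{context} pings earlier AND \code{context}
#' pings later by more than \code{threshold} dB. Flagged samples are
#' replaced by the linear-domain mean of the two comparison samples.
#' Edge pings have only one comparison and are flagged when that single
#' comparison exceeds the threshold. Two adjacent contaminated pings at
#' context 1 shield each other from the two-sided rule; use a larger
#' context (the documented limitation of the ping-comparison design).
#'
#' @param grid an \linkS4class{EchogramGrid}.
#' @param context comparison offset in pings (>= 1, default 2; combined
#'   with the default 5-sample smoothing this is the "5 samples by 5
#'   pings" setting, context 1 with 3 samples the "3 by 3" one).
#' @param smoothWindow vertical smoothing window in samples, odd
#'   (default 5).
#' @param threshold flag threshold, dB (default 10).
#' @return grid with impulse samples repaired and the informational mask
#'   layer "impulse_repaired" recording them.
#' @export
removeImpulseNoise <- function(grid, context = 2L, smoothWindow = 5L,
                               threshold = 10) {
  np <- nrow(grid@Sv)
  if (context < 1) stop("context must be >= 1")
  if (context >= np) stop("context exceeds the ping count")
  if (smoothWindow %% 2 == 0) stop("smoothWindow must be odd")
  grid <- .advanceStage(grid, "impulse_removed")
  sm <- .verticalSmooth(grid@Sv, smoothWindow)
  n <- context
  shift <- function(m, by) { # shift rows (pings) by `by`, NA-filled
    out <- matrix(NA_real_, nrow(m), ncol(m))
    src <- seq_len(nrow(m)) - by
    ok <- src >= 1 & src <= nrow(m)
    out[ok, ] <- m[src[ok], , drop = FALSE]
    out
  }
  prevS <- shift(sm, n); nextS <- shift(sm, -n)
  dPrev <- sm - prevS; dNext <- sm - nextS
  flag <- ifelse(is.na(dPrev), dNext > threshold,
                 ifelse(is.na(dNext), dPrev > threshold,
                        dPrev > threshold & dNext > threshold))
  flag[is.na(flag)] <- FALSE
  flag <- flag & !exclusionMask(grid)
  prevR <- shift(grid@Sv, n); nextR <- shift(grid@Sv, -n)
  repl <- .linToDb((.dbToLin(prevR) + .dbToLin(nextR)) / 2)
  oneSided <- is.na(prevR) | is.na(nextR)
  repl[oneSided] <- ifelse(is.na(prevR[oneSided]), nextR[oneSided],
                           prevR[oneSided])
  grid@Sv[flag] <- repl[flag]
  grid@masks$impulse_repaired <- maskLayer(grid, "impulse_repaired") | flag
  grid
}

#' Resample echogram grids onto the reference frequency's geometry
#'
#' Aligns all frequencies to the reference (38 kHz) transducer: for every
#' reference ping, the nearest-in-time ping of each other frequency within
#' \code{tolerance} seconds is taken (whole columns masked where none
#' exists), and depth bins are linearly interpolated onto the reference
#' bin grid in the linear domain. Existing exclusions propagate into the
#' "resample" mask layer.
#'
#' @param grids list of \linkS4class{EchogramGrid}s.
#' @param reference index or frequency (kHz) of the reference grid;
#'   default the 38 kHz member.
#' @param tolerance maximum ping-time mismatch, s (default 2).
#' @return list of aligned grids (reference included), stage "resampled".
#' @export
resampleToReference <- function(grids, reference = 38, tolerance = 2) {
  freqs <- vapply(grids, function(g) g@frequency, numeric(1))
  ri <- if (reference %in% freqs) which(freqs == reference)[1] else reference
  ref <- grids[[ri]]
  for (g in grids)
    if (.stageRank[g@stage] > .stageRank["raw"])
      stop("pipeline order violation: resampling must come first", call. = FALSE)
  refC <- .binCenters(ref@depthEdges)
  out <- vector("list", length(grids))
  for (k in seq_along(grids)) {
    g <- grids[[k]]
    if (k == ri) {
      g@stage <- "resampled"
      out[[k]] <- g
      next
    }
    if (max(g@pingTime) < min(ref@pingTime) ||
        min(g@pingTime) > max(ref@pingTime))
      stop("no ping-time overlap with the reference grid")
    srcC <- .binCenters(g@depthEdges)
    lin <- .dbToLin(g@Sv)
    lin[exclusionMask(g)] <- NA
    nSv <- matrix(NA_real_, nrow(ref@Sv), ncol(ref@Sv))
    for (p in seq_len(nrow(ref@Sv))) {
      dt <- abs(g@pingTime - ref@pingTime[p])
      j <- which.min(dt)
      if (dt[j] > tolerance) next
      nSv[p, ] <- .linToDb(.interp1NA(srcC, lin[j, ], refC))
    }
    m <- !is.finite(nSv)
    nSv[m] <- -999 # placeholder under mask; never enters any mean
    ng <- echogramGrid(g@frequency, nSv, ref@depthEdges,
                       pingTime = ref@pingTime, latitude = ref@latitude,
                       longitude = ref@longitude, distance = ref@distance,
                       soundSpeed = g@soundSpeed, absorption = g@absorption,
                       stage = "resampled")
    ng <- .addMask(ng, "resample", m)
    out[[k]] <- ng
  }
  names(out) <- names(grids)
  out
}

## box sum over a k1 (rows) x k2 (cols) window, truncated at the edges
.boxSum <- function(m, k1, k2) {
  h1 <- (k1 - 1) %/% 2; h2 <- (k2 - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  lo <- pmax(seq_len(nr) - h1, 1); hi <- pmin(seq_len(nr) + h1, nr)
  m2 <- cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- t(apply(m2, 1, cumsum))
  cs2 <- cbind(0, cs2)
  lo2 <- pmax(seq_len(nc) - h2, 1); hi2 <- pmin(seq_len(nc) + h2, nc)
  cs2[, hi2 + 1, drop = FALSE] - cs2[, lo2, drop = FALSE]
}

#' Smooth Sv with a linear-domain moving mean
#'
#' Moving mean over a window of \code{window[1]} samples (depth) x
#' \code{window[2]} pings, computed in the linear domain over unmasked
#' samples only; masked neighbours are excluded from the denominator, and
#' windows containing no unmasked samples stay masked. Windows truncate at
#' the grid edges.
#'
#' @param grid an \linkS4class{EchogramGrid}.
#' @param window odd window dims c(samples, pings), default c(5, 5).
#' @return smoothed grid, stage "smoothed".
#' @export
smoothSv <- function(grid, window = c(5L, 5L)) {
  if (any(window %% 2 == 0)) stop("window dimensions must be odd")
  grid <- .advanceStage(grid, "smoothed")
  excl <- exclusionMask(grid)
  lin <- .dbToLin(grid@Sv)
  lin[excl] <- 0
  valid <- 1 - excl
  num <- .boxSum(lin, window[2], window[1])   # rows = pings, cols = samples
  den <- .boxSum(valid, window[2], window[1])
  out <- ifelse(den > 0, num / den, NA)
  newSv <- suppressWarnings(.linToDb(out))
  keep <- !excl & den > 0
  grid@Sv[keep] <- newSv[keep]
  grid
}

#' Apply the minimum-Sv threshold
#'
#' Masks samples with Sv strictly below the threshold (default -80 dB
#' re 1 m-1) into the "below_threshold" layer, removing weak signal
#' assumed not to originate from macrozooplankton or nekton. A sample at
#' exactly the threshold is retained.
#'
#' @param grid an \linkS4class{EchogramGrid}.
#' @param threshold minimum Sv, dB (default -80).
#' @return thresholded grid, stage "thresholded".
#' @export
applySvThreshold <- function(grid, threshold = -80) {
  grid <- .advanceStage(grid, "thresholded")
  .addMask(grid, "below_threshold", !exclusionMask(grid) & grid@Sv < threshold)
}

#' Echo-integrate Sv into an MVBS grid
#'
#' Grids the echogram into half-open integration cells of
#' \code{cellDepth} m x \code{cellDist} nmi and computes the mean volume
#' backscattering strength MVBS = 10 log10(mean 10^(Sv/10)) over unmasked
#' samples per cell. The valid-sample fraction is recorded; cells whose
#' fraction falls below \code{minFraction} are undefined (NA, never 0).
#' Trailing partial cells are retained and flagged.
#'
#' @param grid an \linkS4class{EchogramGrid} with along-transect distance.
#' @param cellDepth,cellDist cell size, m x nmi (defaults 3 m x 0.25 nmi,
#'   the coarse statistics grid; use 1 m x 0.1 nmi for composites).
#' @param minFraction minimum unmasked fraction for a defined cell
#'   (default 0.3).
#' @param date date label carried into downstream joins.
#' @return an \linkS4class{MvbsGrid}.
#' @export
computeMvbs <- function(grid, cellDepth = 3, cellDist = 0.25,
                        minFraction = 0.3, date = "") {
  if (cellDepth <= 0 || cellDist <= 0) stop("cell dimensions must be positive")
  sv <- .maskedSv(grid)
  ctr <- .binCenters(grid@depthEdges)
  z0 <- grid@depthEdges[1]
  zIdx <- floor((ctr - z0) / cellDepth) + 1L
  d0 <- min(grid@distance)
  dIdx <- floor((grid@distance - d0) / cellDist) + 1L
  nz <- max(zIdx); nd <- max(dIdx)
  lin <- .dbToLin(sv)
  mvbsM <- matrix(NA_real_, nd, nz)
  vf <- matrix(0, nd, nz)
  for (i in seq_len(nd)) {
    rows <- dIdx == i
    for (j in seq_len(nz)) {
      cols <- zIdx == j
      vals <- lin[rows, cols, drop = FALSE]
      nTot <- length(vals); nOk <- sum(!is.na(vals))
      vf[i, j] <- if (nTot) nOk / nTot else 0
      if (nTot && nOk / nTot >= minFraction && nOk > 0)
        mvbsM[i, j] <- .linToDb(mean(vals, na.rm = TRUE))
    }
  }
  zEdges <- z0 + (0:nz) * cellDepth
  zEdges[nz + 1] <- min(zEdges[nz + 1], max(grid@depthEdges))
  dEdges <- d0 + (0:nd) * cellDist
  dMax <- max(grid@distance) + if (nrow(sv) > 1) mean(diff(grid@distance)) else cellDist
  lat <- lon <- rep(NA_real_, nd)
  for (i in seq_len(nd)) {
    rows <- dIdx == i
    lat[i] <- mean(grid@latitude[rows]); lon[i] <- mean(grid@longitude[rows])
  }
  new("MvbsGrid", frequency = grid@frequency, depthEdges = zEdges,
      distEdges = dEdges, mvbs = mvbsM, validFraction = vf,
      partialDist = c(rep(FALSE, nd - 1), dEdges[nd + 1] > dMax + 1e-9),
      partialDepth = c(rep(FALSE, nz - 1),
                       z0 + nz * cellDepth > max(grid@depthEdges) + 1e-9),
      latitude = lat, longitude = lon, date = date)
}

#' Run the full cleaning chain on a set of echogram grids
#'
#' Convenience wrapper applying the chain in its enforced order: resample
#' to the 38 kHz geometry, surface and bottom exclusion, background-noise
#' removal, impulse-noise removal, smoothing, minimum-Sv threshold. Stages
#' can be disabled individually.
#'
#' @param grids list of \linkS4class{EchogramGrid}s (one per frequency).
#' @param params list of per-stage parameter lists; see
#'   \code{\link{defaultPipelineConfig}} for the defaults and units.
#' @param enable named logical vector switching stages on/off.
#' @return list with \code{grids} (cleaned) and \code{noise} (per-frequency
#'   \linkS4class{NoiseEstimate}s).
#' @export
preprocessEchograms <- function(grids, params = defaultPipelineConfig()$preprocess,
                                enable = c(resample = TRUE, surface = TRUE,
                                           bottom = TRUE, noise = TRUE,
                                           impulse = TRUE, smooth = TRUE,
                                           threshold = TRUE)) {
  if (isTRUE(enable[["resample"]]))
    grids <- resampleToReference(grids, tolerance = params$resampleTolerance)
  noise <- list()
  for (k in seq_along(grids)) {
    g <- grids[[k]]
    if (isTRUE(enable[["surface"]]))
      g <- excludeSurface(g, a = params$transducerRadius,
                          buffer = params$surfaceBuffer)
    if (isTRUE(enable[["bottom"]]))
      g <- detectAndExcludeBottom(g, threshold = params$bottomThreshold,
                                  minDepth = params$bottomMinDepth,
                                  offset = params$bottomOffset)
    if (isTRUE(enable[["noise"]])) {
      bn <- removeBackgroundNoise(g, cell = params$noiseCell,
                                  snrThreshold = params$snrThreshold,
                                  maxNoise = params$maxNoise)
      g <- bn$grid
      noise[[as.character(g@frequency)]] <- bn$noise
    }
    if (isTRUE(enable[["impulse"]]))
      g <- removeImpulseNoise(g, context = params$impulseContext,
                              smoothWindow = params$impulseSmooth,
                              threshold = params$impulseThreshold)
    if (isTRUE(enable[["smooth"]]))
      g <- smoothSv(g, window = params$smoothWindow)
    if (isTRUE(enable[["threshold"]]))
      g <- applySvThreshold(g, threshold = params$svThreshold)
    grids[[k]] <- g
  }
  list(grids = grids, noise = noise)
}
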