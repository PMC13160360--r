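## Synthetic-data generators: echograms, CTD transects, SST series and
## trawl catches with planted ground truth. One master seed; each
## simulator derives its own sub-stream so adding one call never shifts
## the others.

.subSeed <- function(seed, k) (seed * 7L + k) %% 2147483647L

#' Define a fish-school target
#'
#' A rectangular scattering target whose 120-38 kHz response difference
#' is at most 5 dB (the fish frequency-response regime).
#'
#' @param dist along-transect extent c(from, to), nmi.
#' @param depth depth extent c(top, bottom), m.
#' @param sv38 peak Sv at 38 kHz, dB re 1 m-1.
#' @param d18,d120 frequency-response offsets Sv(18)-Sv(38) and
#'   Sv(120)-Sv(38), dB (d120 must be <= 5).
#' @return target description list.
#' @export
fishSchool <- function(dist, depth, sv38 = -55, d18 = -2, d120 = 2) {
  list(type = "fish", dist = dist, depth = depth, sv38 = sv38,
       d18 = d18, d120 = d120)
}

#' Define a macrozooplankton-layer target
#'
#' A rectangular scattering layer whose 120-38 kHz response difference
#' exceeds 10 dB (the macrozooplankton regime).
#'
#' @inheritParams fishSchool
#' @param d120 Sv(120)-Sv(38) offset, dB (must be > 10).
#' @return target description list.
#' @export
zooplanktonLayer <- function(dist, depth, sv38 = -76, d18 = -8, d120 = 12) {
  list(type = "zooplankton", dist = dist, depth = depth, sv38 = sv38,
       d18 = d18, d120 = d120)
}

#' Construct a simulation configuration
#'
#' Builds a validated \linkS4class{SimulationConfig}. The defaults are the
#' package's reference scene, mirroring a high-latitude frontal survey at
#' desk scale: a 600-ping northbound transect at 0.1 nmi ping spacing
#' (76.7-77.7 deg N along 29.5 deg E), 250 m of water over a 230 m seabed,
#' a logistic thermal front at 77.2 deg N of width 0.03 deg separating
#' 3.2 deg C / 35.2 g kg-1 southern water from -1.8 deg C / 34.3 g kg-1
#' northern water, ice edges north of the front, one shallow and one deep
#' fish school plus one macrozooplankton layer north of the front, and
#' TVG-amplified per-frequency noise floors about 30 dB below the planted
#' signals.
#'
#' @param seed integer master seed.
#' @param transect,front,noise,community named lists overriding individual
#'   defaults (see \linkS4class{SimulationConfig} for the fields).
#' @param targets list of targets (\code{\link{fishSchool}},
#'   \code{\link{zooplanktonLayer}}); default three-target scene.
#' @param seabed seabed depth, m (scalar or per ping).
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, transect = list(), front = list(),
                             noise = list(), targets = NULL, seabed = 230,
                             community = list()) {
  tr <- utils::modifyList(list(
    latStart = 76.7, nPings = 600L, pingSpacing = 0.1, maxDepth = 250,
    binSize = 1, longitude = 29.5, date = "2022-05-01", pingInterval = 1,
    timeOffsets = c(f18 = 0.15, f38 = 0, f120 = 0.3)), transect)
  fr <- utils::modifyList(list(
    lat = 77.2, width = 0.03, tSouth = 3.2, tNorth = -1.8,
    sSouth = 35.2, sNorth = 34.3, mixedLayer = 20, surfaceArm = FALSE,
    surfaceLat = NULL, openIce = 77.45, closedIce = 77.6), front)
  no <- utils::modifyList(list(
    floors = c(f18 = -135, f38 = -132, f120 = -130),
    impulseFraction = 0.02, impulseAmplitude = 20, svJitter = 1,
    surfaceSv = -40), noise)
  if (is.null(targets))
    targets <- list(
      fishSchool(dist = c(5, 15), depth = c(60, 100), sv38 = -55),
      fishSchool(dist = c(10, 40), depth = c(170, 210), sv38 = -62,
                 d18 = -1, d120 = 1),
      zooplanktonLayer(dist = c(31, 55), depth = c(30, 70), sv38 = -76))
  cm <- utils::modifyList(list(
    taxa = c("euphausiids", "amphipods", "chaetognaths", "pteropods",
             "ctenophores", "hydrozoans", "MMZ"),
    south = c(0.30, 0.05, 0.10, 0.03, 0.05, 0.07, 0.40),
    north = c(0.08, 0.25, 0.12, 0.15, 0.10, 0.10, 0.20),
    effect = 1, nStations = 12L, drawSize = 400L, mouthArea = 1,
    towDistance = 1100,
    unitWeight = c(0.12, 0.05, 0.02, 0.01, 0.5, 0.8, 0.002)), community)
  new("SimulationConfig", seed = as.integer(seed), transect = tr, front = fr,
      noise = no, targets = targets, seabed = seabed, community = cm)
}

## logistic front shape shared by the CTD, SST and echogram generators
.frontField <- function(lat, latFront, width, south, north) {
  if (width <= 0) ifelse(lat >= latFront, north, south)
  else south + (north - south) * stats::plogis((lat - latFront) / width)
}

#' Simulate a two-water-mass CTD transect with a logistic thermal front
#'
#' Temperature below the mixed layer follows
#' T(lat) = T_south + (T_north - T_south) * logistic((lat - lat_front)/w);
#' salinity is analogous; an optional cold surface arm overlays northern
#' water in the upper 50 m south of the front. Small seeded Gaussian
#' sensor noise (sd 0.002, the level of binned pumped-CTD data) is added and density follows the linearized
#' equation of state. Ground truth (front latitude and width) is returned
#' alongside.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param latGrid,depthGrid output grids; defaults 0.01 deg over the
#'   transect (the resolution of a towed-profiler section, matching the
#'   front-localization grid) and 2 m over the water column.
#' @return list: \code{section} (a \linkS4class{CtdSection}) and
#'   \code{truth} (frontLat, width).
#' @export
simulateCtdTransect <- function(config, latGrid = NULL, depthGrid = NULL) {
  tr <- config@transect; fr <- config@front
  latEnd <- tr$latStart + tr$nPings * tr$pingSpacing / 60
  if (is.null(latGrid)) latGrid <- seq(tr$latStart, latEnd, by = 0.01)
  if (is.null(depthGrid)) depthGrid <- seq(0, tr$maxDepth, by = 2)
  if (length(unique(latGrid)) < 2)
    stop("degenerate transect: at least two distinct latitudes required")
  set.seed(.subSeed(config@seed, 11L))
  Tlat <- .frontField(latGrid, fr$lat, fr$width, fr$tSouth, fr$tNorth)
  Slat <- .frontField(latGrid, fr$lat, fr$width, fr$sSouth, fr$sNorth)
  CT <- matrix(Tlat, length(latGrid), length(depthGrid))
  SA <- matrix(Slat, length(latGrid), length(depthGrid))
  if (isTRUE(fr$surfaceArm)) {
    arm <- outer(latGrid <= fr$lat, depthGrid <= 50, `&`)
    CT[arm] <- fr$tNorth
    SA[arm] <- fr$sNorth
  }
  ## sensor noise at the level of a pumped CTD (temperature/conductivity
  ## short-term noise of order 0.001-0.002 on binned data)
  CT <- CT + matrix(stats::rnorm(length(CT), sd = 0.002), nrow(CT))
  SA <- SA + matrix(stats::rnorm(length(SA), sd = 0.002), nrow(SA))
  sec <- new("CtdSection", latitude = latGrid, depth = depthGrid, CT = CT,
             SA = SA, sigmaTheta = linearSigmaTheta(CT, SA),
             mask = matrix(FALSE, nrow(CT), ncol(CT)))
  list(section = sec, truth = list(frontLat = fr$lat, width = fr$width))
}

#' Simulate a satellite SST series across the front
#'
#' Surface temperature along the transect: the logistic front shape at the
#' (surface) front latitude plus seeded Gaussian noise (sd 0.05).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param resolution latitude step, deg (default 0.02).
#' @return data.frame: date, lat, sst; truth front latitude as attribute
#'   \code{"frontLat"}.
#' @export
simulateSstSeries <- function(config, resolution = 0.02) {
  tr <- config@transect; fr <- config@front
  latEnd <- tr$latStart + tr$nPings * tr$pingSpacing / 60
  lat <- seq(tr$latStart, latEnd, by = resolution)
  fLat <- if (is.null(fr$surfaceLat)) fr$lat else fr$surfaceLat
  set.seed(.subSeed(config@seed, 44L))
  sst <- .frontField(lat, fLat, fr$width, fr$tSouth, fr$tNorth) +
    stats::rnorm(length(lat), sd = 0.05)
  out <- data.frame(date = tr$date, lat = lat, sst = sst)
  attr(out, "frontLat") <- fLat
  out
}

#' Simulate three-frequency echograms with planted targets
#'
#' For each frequency, Sv = 10 log10(10^(signal/10) + 10^(noise/10)) with
#' the TVG-amplified noise floor Sv_noise(r) = N0 + 20 log10 r + 2 a r
#' (additive in the linear domain, matching the subtraction model of
#' background-noise removal). Targets are painted with their per-frequency
#' offsets, a strong seabed echo fills bins below the seabed, near-surface
#' contamination fills the top 3 m, whole pings at seeded indices gain the
#' impulse amplitude, and Gaussian dB jitter (sd \code{svJitter}) emulates
#' sample-level variability.
#'
#' @param config a \linkS4class{SimulationConfig} (seabed must lie below
#'   every target).
#' @param addNoise paint noise floor, jitter and impulses (default TRUE);
#'   FALSE returns the pure signal fields (for offset-conservation
#'   checks).
#' @return list: \code{grids} (named list of \linkS4class{EchogramGrid}s,
#'   f18/f38/f120) and \code{truth} (per-sample class matrix with levels
#'   FISH / ZOO / SEABED / NONE, noise floors, impulse ping indices per
#'   frequency, front latitude, target list).
#' @export
simulateEchograms <- function(config, addNoise = TRUE) {
  tr <- config@transect; fr <- config@front; no <- config@noise
  np <- tr$nPings
  edges <- seq(0, tr$maxDepth, by = tr$binSize)
  ctr <- .binCenters(edges)
  dist <- (seq_len(np) - 1) * tr$pingSpacing
  lat <- tr$latStart + dist / 60
  seabed <- rep_len(config@seabed, np)
  for (tg in config@targets)
    if (max(tg$depth) > min(seabed))
      stop("target extends below the seabed")
  freqs <- c(f18 = 18, f38 = 38, f120 = 120)
  alpha <- vapply(freqs, absorptionCoefficient,
                  T = mean(c(fr$tSouth, fr$tNorth)), S = 34.8, z = 100,
                  pH = 8, FUN.VALUE = numeric(1))
  ## per-sample signal class truth (shared geometry across frequencies)
  truthClass <- matrix("NONE", np, length(ctr))
  sig38 <- matrix(-Inf, np, length(ctr))
  offsets <- list(f18 = matrix(0, np, length(ctr)),
                  f120 = matrix(0, np, length(ctr)))
  for (tg in config@targets) {
    rows <- dist >= tg$dist[1] & dist < tg$dist[2]
    cols <- ctr >= tg$depth[1] & ctr < tg$depth[2]
    sig38[rows, cols] <- tg$sv38
    offsets$f18[rows, cols] <- tg$d18
    offsets$f120[rows, cols] <- tg$d120
    truthClass[rows, cols] <- if (tg$type == "fish") "FISH" else "ZOO"
  }
  bed <- outer(seabed, ctr, function(s, z) z >= s)
  truthClass[bed] <- "SEABED"
  surf <- matrix(rep(ctr < 3, each = np), np)
  set.seed(.subSeed(config@seed, 22L))
  grids <- list(); impulses <- list()
  for (nm in names(freqs)) {
    f <- freqs[[nm]]
    sig <- sig38 + switch(nm, f18 = offsets$f18, f120 = offsets$f120,
                          f38 = 0)
    sig[sig38 == -Inf] <- -Inf
    sig[bed] <- -20
    sig[surf & !bed] <- pmax(sig[surf & !bed], no$surfaceSv)
    if (addNoise) {
      svNoise <- no$floors[[nm]] + 20 * log10(pmax(ctr, 1e-6)) +
        2 * alpha[[nm]] * ctr
      sv <- .linToDb(.dbToLin(sig) +
                       matrix(rep(.dbToLin(svNoise), each = np), np))
      sv <- sv + matrix(stats::rnorm(length(sv), sd = no$svJitter), np)
      nImp <- round(no$impulseFraction * np)
      imp <- if (nImp > 0) sort(sample.int(np, nImp)) else integer()
      sv[imp, ] <- sv[imp, ] + no$impulseAmplitude
      impulses[[nm]] <- imp
    } else {
      sv <- sig
      impulses[[nm]] <- integer()
    }
    grids[[nm]] <- echogramGrid(
      f, sv, edges,
      pingTime = (seq_len(np) - 1) * tr$pingInterval + tr$timeOffsets[[nm]],
      latitude = lat, longitude = rep(tr$longitude, np), distance = dist,
      soundSpeed = 1480, absorption = alpha[[nm]])
  }
  list(grids = grids,
       truth = list(class = truthClass, noiseFloors = no$floors,
                    impulsePings = impulses, frontLat = fr$lat,
                    targets = config@targets, seabed = seabed,
                    depthEdges = edges, distance = dist))
}

#' Simulate trawl catches from two frontal communities
#'
#' Stations are spread along the transect and assigned to the southern or
#' northern community by position relative to the front. Taxon counts are
#' multinomial draws of the configured draw size; the effective northern
#' composition is (1 - effect) * south + effect * north, so effect 0 is an
#' exact community null. Volumes carry small seeded jitter; dry weights
#' are counts times per-taxon unit weights with lognormal noise.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list: \code{catch} (data.frame: station, latitude, water_mass,
#'   mouth_area_m2, tow_distance_m, one count column per taxon and
#'   dw_<taxon> dry weights in g) and \code{truth} (per-station
#'   composition).
#' @export
simulateTrawlCatches <- function(config) {
  cm <- config@community; tr <- config@transect; fr <- config@front
  latEnd <- tr$latStart + tr$nPings * tr$pingSpacing / 60
  lats <- seq(tr$latStart + 0.02, latEnd - 0.02, length.out = cm$nStations)
  pN <- (1 - cm$effect) * cm$south + cm$effect * cm$north
  pN <- pN / sum(pN)
  set.seed(.subSeed(config@seed, 33L))
  counts <- matrix(0L, cm$nStations, length(cm$taxa),
                   dimnames = list(NULL, cm$taxa))
  probs <- matrix(0, cm$nStations, length(cm$taxa),
                  dimnames = list(NULL, cm$taxa))
  mass <- ifelse(lats >= fr$lat, "north", "south")
  for (i in seq_len(cm$nStations)) {
    p <- if (mass[i] == "north") pN else cm$south
    probs[i, ] <- p
    counts[i, ] <- stats::rmultinom(1, cm$drawSize, p)
  }
  towDist <- cm$towDistance * stats::runif(cm$nStations, 0.9, 1.1)
  dw <- sweep(counts, 2, cm$unitWeight, `*`) *
    matrix(stats::rlnorm(length(counts), 0, 0.1), nrow(counts))
  catch <- data.frame(station = sprintf("st%02d", seq_len(cm$nStations)),
                      latitude = lats, water_mass = mass,
                      mouth_area_m2 = cm$mouthArea, tow_distance_m = towDist)
  catch <- cbind(catch, as.data.frame(counts))
  dwDf <- as.data.frame(dw); names(dwDf) <- paste0("dw_", cm$taxa)
  catch <- cbind(catch, dwDf)
  list(catch = catch, truth = list(probs = probs, water_mass = mass,
                                   effect = cm$effect))
}
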