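## S4 containers for gridded acoustic and hydrographic data.
##
## Conventions used throughout the package (stated once, used everywhere):
##  - depth is positive down, in metres; depth bins are half-open [top, bottom)
##  - Sv and MVBS are dB re 1 m-1; all averaging of dB quantities happens in
##    the linear (power) domain
##  - masks are logical matrices, TRUE = excluded; no stage ever unmasks
##  - along-transect distance is in nautical miles (nmi)

#' Processing stages of the echogram cleaning chain
#'
#' The cleaning chain is ordered: resample, surface/bottom exclusion,
#' background-noise removal, impulse-noise removal, smoothing, Sv threshold.
#' Each operation records the stage it produced; applying an earlier
#' operation to a grid that has already passed a later stage is a contract
#' error, which is how the pipeline order is enforced.
#'
#' @keywords internal
.stageRank <- c(raw = 0L, resampled = 1L, excluded = 2L, noise_removed = 3L,
                impulse_removed = 4L, smoothed = 5L, thresholded = 6L)

## mask layers that do NOT exclude samples from averaging (informational)
.infoLayers <- "impulse_repaired"

#' EchogramGrid: one frequency's Sv matrix over pings and depth bins
#'
#' Volume-backscattering strength (Sv, dB re 1 m-1) for a single
#' echosounder frequency, with ping time/position, along-transect distance,
#' half-open depth-bin edges, named exclusion-mask layers and the sound
#' speed / absorption used for time-varied-gain calculations.
#'
#' @slot frequency transmit frequency, kHz.
#' @slot Sv numeric matrix, pings x depth bins, dB re 1 m-1.
#' @slot pingTime numeric seconds (arbitrary epoch), one per ping.
#' @slot latitude,longitude decimal degrees, one per ping.
#' @slot distance along-transect distance, nmi, one per ping.
#' @slot depthEdges strictly increasing bin edges, m; bins are [top, bottom).
#' @slot masks named list of logical matrices (TRUE = excluded); the layer
#'   \code{impulse_repaired} is informational and does not exclude samples.
#' @slot lines named list of per-ping depth lines (e.g. surface, bottom), m.
#' @slot soundSpeed sound speed used for ranges, m s-1.
#' @slot absorption absorption coefficient at this frequency, dB m-1.
#' @slot stage processing stage (see the cleaning-chain order above).
#' @exportClass EchogramGrid
setClass("EchogramGrid", representation(
  frequency = "numeric", Sv = "matrix", pingTime = "numeric",
  latitude = "numeric", longitude = "numeric", distance = "numeric",
  depthEdges = "numeric", masks = "list", lines = "list",
  soundSpeed = "numeric", absorption = "numeric", stage = "character"))

setValidity("EchogramGrid", function(object) {
  np <- nrow(object@Sv); nb <- ncol(object@Sv)
  msg <- character()
  if (length(object@depthEdges) != nb + 1L)
    msg <- c(msg, "depthEdges must have ncol(Sv) + 1 entries")
  if (any(diff(object@depthEdges) <= 0))
    msg <- c(msg, "depthEdges must be strictly increasing")
  for (v in c("pingTime", "latitude", "longitude", "distance"))
    if (length(slot(object, v)) != np)
      msg <- c(msg, sprintf("%s must have one entry per ping", v))
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), dim(object@Sv)))
      msg <- c(msg, sprintf("mask layer '%s' must be a logical matrix of Sv shape", nm))
  }
  if (!object@stage %in% names(.stageRank))
    msg <- c(msg, "unknown processing stage")
  if (length(msg)) msg else TRUE
})

#' Construct an EchogramGrid
#'
#' @param frequency kHz.
#' @param Sv pings x bins matrix, dB re 1 m-1.
#' @param depthEdges strictly increasing bin edges, m.
#' @param pingTime,latitude,longitude,distance per-ping vectors; sensible
#'   defaults are filled in when omitted.
#' @param soundSpeed,absorption sound speed (m s-1) and absorption (dB m-1)
#'   used for range and TVG computations.
#' @param stage processing stage label, default \code{"raw"}.
#' @return an \linkS4class{EchogramGrid}.
#' @export
echogramGrid <- function(frequency, Sv, depthEdges,
                         pingTime = seq_len(nrow(Sv)) - 1,
                         latitude = rep(0, nrow(Sv)),
                         longitude = rep(0, nrow(Sv)),
                         distance = (seq_len(nrow(Sv)) - 1) * 0.1,
                         soundSpeed = 1480, absorption = 0.01,
                         stage = "raw") {
  new("EchogramGrid", frequency = frequency, Sv = Sv,
      pingTime = as.numeric(pingTime), latitude = latitude,
      longitude = longitude, distance = distance,
      depthEdges = depthEdges, masks = list(), lines = list(),
      soundSpeed = soundSpeed, absorption = absorption, stage = stage)
}

#' NoiseEstimate: per ping-block background-noise level
#'
#' @slot frequency kHz.
#' @slot noise estimated noise at the receiver per ping block, dB.
#' @slot blockStart first ping index (1-based) of each block.
#' @slot cell integration cell used, c(pings, samples).
#' @slot snrThreshold SNR threshold applied, dB.
#' @slot maxNoise cap applied to the noise estimate, dB.
#' @exportClass NoiseEstimate
setClass("NoiseEstimate", representation(
  frequency = "numeric", noise = "numeric", blockStart = "integer",
  cell = "integer", snrThreshold = "numeric", maxNoise = "numeric"))

setValidity("NoiseEstimate", function(object) {
  if (any(object@noise > object@maxNoise + 1e-9, na.rm = TRUE))
    "noise estimates exceed the configured cap" else TRUE
})

#' CtdProfile: one station's depth series of hydrographic properties
#'
#' Conservative temperature, absolute salinity and potential density anomaly
#' against strictly increasing depth. Inputs are assumed already converted to
#' TEOS-10 variables (conversion from practical salinity / in-situ
#' temperature is out of scope); when density is unavailable the linearized
#' equation of state \code{\link{linearSigmaTheta}} may be used.
#'
#' @slot station station identifier.
#' @slot latitude,longitude decimal degrees.
#' @slot time observation time label.
#' @slot depth m, positive down, strictly increasing.
#' @slot CT conservative temperature, deg C.
#' @slot SA absolute salinity, g kg-1.
#' @slot sigmaTheta potential density anomaly, kg m-3.
#' @exportClass CtdProfile
setClass("CtdProfile", representation(
  station = "character", latitude = "numeric", longitude = "numeric",
  time = "character", depth = "numeric", CT = "numeric", SA = "numeric",
  sigmaTheta = "numeric"))

setValidity("CtdProfile", function(object) {
  msg <- character()
  n <- length(object@depth)
  if (length(object@CT) != n || length(object@SA) != n ||
      length(object@sigmaTheta) != n)
    msg <- c(msg, "depth, CT, SA and sigmaTheta must have equal length")
  if (n > 1 && any(diff(object@depth) <= 0))
    msg <- c(msg, "depth must be strictly increasing")
  if (any(object@SA <= 0, na.rm = TRUE))
    msg <- c(msg, "SA must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a CtdProfile
#'
#' @param station station id.
#' @param depth,CT,SA equal-length vectors (m, deg C, g kg-1).
#' @param sigmaTheta potential density anomaly; computed with
#'   \code{\link{linearSigmaTheta}} when omitted.
#' @param latitude,longitude,time position and time metadata.
#' @return a \linkS4class{CtdProfile}.
#' @export
ctdProfile <- function(station, depth, CT, SA, sigmaTheta = NULL,
                       latitude = 0, longitude = 0, time = "") {
  if (is.null(sigmaTheta)) sigmaTheta <- linearSigmaTheta(CT, SA)
  new("CtdProfile", station = as.character(station), latitude = latitude,
      longitude = longitude, time = time, depth = depth, CT = CT, SA = SA,
      sigmaTheta = sigmaTheta)
}

#' CtdSection: profiles interpolated onto a latitude x depth grid
#'
#' @slot latitude latitude grid, decimal degrees, strictly increasing.
#' @slot depth depth grid, m, strictly increasing.
#' @slot CT,SA,sigmaTheta latitude x depth matrices.
#' @slot mask logical latitude x depth matrix, TRUE = outside the profile
#'   hull (no extrapolation is performed); masked cells carry NA.
#' @exportClass CtdSection
setClass("CtdSection", representation(
  latitude = "numeric", depth = "numeric", CT = "matrix", SA = "matrix",
  sigmaTheta = "matrix", mask = "matrix"))

setValidity("CtdSection", function(object) {
  msg <- character()
  dm <- c(length(object@latitude), length(object@depth))
  for (v in c("CT", "SA", "sigmaTheta", "mask"))
    if (!identical(dim(slot(object, v)), as.integer(dm)))
      msg <- c(msg, sprintf("%s must be a latitude x depth matrix", v))
  if (any(diff(object@latitude) <= 0) || any(diff(object@depth) <= 0))
    msg <- c(msg, "latitude and depth grids must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' MvbsGrid: echo-integrated mean volume backscattering strength
#'
#' MVBS (dB re 1 m-1) over half-open integration cells of configurable
#' depth (m) x along-transect distance (nmi) size. MVBS is only defined
#' where the fraction of unmasked samples meets the configured minimum;
#' undefined cells are NA, never 0. Trailing partial cells are retained
#' and flagged.
#'
#' @slot frequency kHz.
#' @slot depthEdges,distEdges cell edges (m, nmi), half-open [l, r).
#' @slot mvbs distance x depth matrix, dB re 1 m-1 (NA where undefined).
#' @slot validFraction fraction of unmasked samples per cell.
#' @slot partialDist,partialDepth flags for trailing partial cells.
#' @slot latitude,longitude mean ping position per distance cell.
#' @slot date date label carried to downstream joins.
#' @exportClass MvbsGrid
setClass("MvbsGrid", representation(
  frequency = "numeric", depthEdges = "numeric", distEdges = "numeric",
  mvbs = "matrix", validFraction = "matrix", partialDist = "logical",
  partialDepth = "logical", latitude = "numeric", longitude = "numeric",
  date = "character"))

setValidity("MvbsGrid", function(object) {
  nd <- length(object@distEdges) - 1L; nz <- length(object@depthEdges) - 1L
  if (!identical(dim(object@mvbs), c(nd, nz)))
    return("mvbs must be a (distance cells) x (depth cells) matrix")
  if (!identical(dim(object@validFraction), dim(object@mvbs)))
    return("validFraction must match mvbs shape")
  TRUE
})

#' ClassifiedGrid: integration cells labelled fish / macrozooplankton
#'
#' Frequency-differencing classification of co-registered 38 and 120 kHz
#' MVBS grids. Cells shallower than the multifrequency depth limit are
#' classified from the dB difference MVBS(120) - MVBS(38); deeper cells are
#' assigned to fish from 38 kHz alone (the 120 kHz observational range
#' limit). Classes are exclusive and exhaustive.
#'
#' @slot depthEdges,distEdges cell edges shared with the input grids.
#' @slot delta MVBS(120) - MVBS(38) per cell, dB (NA where unavailable).
#' @slot class character matrix: FISH, MACROZOOPLANKTON, UNCLASSIFIED or
#'   EXCLUDED.
#' @slot stratum per depth cell: SHALLOW (top edge < split) or DEEP.
#' @slot mvbs38,mvbs120 the input MVBS matrices (120 kHz NA below split).
#' @slot splitDepth the multifrequency depth limit, m (default 150).
#' @slot latitude,longitude,date carried from the 38 kHz grid.
#' @exportClass ClassifiedGrid
setClass("ClassifiedGrid", representation(
  depthEdges = "numeric", distEdges = "numeric", delta = "matrix",
  cellClass = "matrix", stratum = "character", mvbs38 = "matrix",
  mvbs120 = "matrix", splitDepth = "numeric", latitude = "numeric",
  longitude = "numeric", date = "character"))

setValidity("ClassifiedGrid", function(object) {
  ok <- object@cellClass %in% c("FISH", "MACROZOOPLANKTON", "UNCLASSIFIED", "EXCLUDED")
  if (!all(ok)) return("unknown cell class label")
  deep <- object@stratum == "DEEP"
  if (any(object@cellClass[, deep, drop = FALSE] == "MACROZOOPLANKTON"))
    return("DEEP cells cannot be MACROZOOPLANKTON (120 kHz range limit)")
  TRUE
})

#' RgbComposite: three-frequency colour composite of MVBS
#'
#' @slot rgb numeric array (distance x depth x 3), values in [0, 255];
#'   channel order red = 18 kHz, green = 38 kHz, blue = 120 kHz; missing
#'   data rendered 0.
#' @slot depthEdges,distEdges cell edges of the underlying grids.
#' @slot gamma gamma-normalization exponent used.
#' @slot channels channel -> frequency map.
#' @exportClass RgbComposite
setClass("RgbComposite", representation(
  rgb = "array", depthEdges = "numeric", distEdges = "numeric",
  gamma = "numeric", channels = "numeric"))

setValidity("RgbComposite", function(object) {
  if (length(dim(object@rgb)) != 3 || dim(object@rgb)[3] != 3)
    return("rgb must be a distance x depth x 3 array")
  if (any(object@rgb < 0 | object@rgb > 255, na.rm = TRUE))
    return("rgb values must lie in [0, 255]")
  TRUE
})

#' SimulationConfig: scene description for the synthetic-data generators
#'
#' Holds the transect geometry, the logistic thermal front, per-frequency
#' noise model, planted scattering targets, seabed and trawl-community
#' parameters. Defaults describe the package's reference scene: a 600-ping,
#' 0.1 nmi-spaced northbound transect over 250 m of water with the
#' subsurface front at 77.2 deg N. Use \code{\link{simulationConfig}} to
#' construct one.
#'
#' @slot seed integer master seed; each simulator derives its own
#'   sub-stream so adding one simulator call does not shift the others.
#' @slot transect list: latStart (deg N), nPings, pingSpacing (nmi),
#'   maxDepth (m), binSize (m), longitude (deg E), date, pingInterval (s),
#'   timeOffsets (s per frequency).
#' @slot front list: lat (deg N), width (deg), tSouth/tNorth (deg C),
#'   sSouth/sNorth (g kg-1), mixedLayer (m), surfaceArm (logical),
#'   openIce/closedIce (deg N ice-edge latitudes).
#' @slot noise list: floors (dB at the receiver, named f18/f38/f120),
#'   impulseFraction, impulseAmplitude (dB), svJitter (dB sd).
#' @slot targets list of targets from \code{\link{fishSchool}} /
#'   \code{\link{zooplanktonLayer}}.
#' @slot seabed seabed depth, m (scalar or one value per ping).
#' @slot community list: taxa, south/north relative-abundance vectors,
#'   effect in [0,1], nStations, drawSize, mouthArea (m2), towDistance (m),
#'   unitWeight (g per individual per taxon).
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  seed = "integer", transect = "list", front = "list", noise = "list",
  targets = "list", seabed = "numeric", community = "list"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  tr <- object@transect
  if (tr$nPings < 2) msg <- c(msg, "nPings must be >= 2")
  if (tr$binSize <= 0 || tr$maxDepth <= tr$binSize)
    msg <- c(msg, "depth bins must be strictly increasing")
  no <- object@noise
  if (no$impulseFraction < 0 || no$impulseFraction > 1)
    msg <- c(msg, "impulseFraction must lie in [0, 1]")
  for (tg in object@targets) {
    if (tg$type == "fish" && tg$d120 > 5)
      msg <- c(msg, "fish targets must have dMVBS(120-38) <= 5 dB")
    if (tg$type == "zooplankton" && tg$d120 <= 10)
      msg <- c(msg, "zooplankton targets must have dMVBS(120-38) > 10 dB")
  }
  cm <- object@community
  if (abs(sum(cm$south) - 1) > 1e-8 || abs(sum(cm$north) - 1) > 1e-8)
    msg <- c(msg, "community relative abundances must sum to 1")
  if (cm$mouthArea <= 0 || cm$towDistance <= 0)
    msg <- c(msg, "trawl volume (mouth area x tow distance) must be positive")
  if (length(msg)) msg else TRUE
})
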