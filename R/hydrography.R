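## CTD calibration, water-mass classification, stratification and
## front / ice-edge geometry.

#' Linearized equation of state for potential density anomaly
#'
#' First-order expansion of the equation of state around cold Arctic shelf
#' water (Theta = 0 deg C, SA = 34.8 g kg-1, sigma-theta = 27.95 kg m-3)
#' with thermal expansion 0.06 kg m-3 K-1 and haline contraction
#' 0.78 kg m-3 (g/kg)-1. Used by the synthetic-data generators and as a
#' fallback when input CSVs carry no density column; it is a linearization,
#' not a TEOS-10 evaluation.
#'
#' @param CT conservative temperature, deg C.
#' @param SA absolute salinity, g kg-1.
#' @return potential density anomaly sigma-theta, kg m-3.
#' @export
linearSigmaTheta <- function(CT, SA) {
  27.95 - 0.06 * CT + 0.78 * (SA - 34.8)
}

#' Water-mass class labels
#' @export
waterMassLevels <- c("POLAR", "WARM_POLAR", "ATLANTIC", "MODIFIED_ATLANTIC",
                     "INTERMEDIATE", "CBSDW", "UNCLASSIFIED")

#' Rule-based water-mass classification
#'
#' Classifies each (SA, Theta, sigma-theta) triple into one of the Barents
#' Sea water masses: Atlantic (SA >= 35.06, Theta > 2), Modified Atlantic
#' (SA >= 35.06, 0 < Theta <= 2), Warm Polar (SA < 35.06, Theta > 0) and,
#' for Theta <= 0, Polar when sigma-theta <= 27.97, otherwise Intermediate
#' when Theta > -1.1 and Cold Barents Sea Dense Water (CBSDW) when
#' Theta <= -1.1. The cold-water rows overlap as printed in the source
#' criteria; density is checked first and then temperature, which makes the
#' classes mutually exclusive and the function total.
#'
#' @param SA absolute salinity, g kg-1.
#' @param CT conservative temperature Theta, deg C.
#' @param sigmaTheta potential density anomaly, kg m-3.
#' @return factor with levels \code{\link{waterMassLevels}}.
#' @examples
#' classifyWaterMass(35.10, 2.5, 27.5)   # ATLANTIC
#' classifyWaterMass(34.50, -0.5, 27.50) # POLAR
#' @export
classifyWaterMass <- function(SA, CT, sigmaTheta) {
  n <- max(length(SA), length(CT), length(sigmaTheta))
  SA <- rep_len(SA, n); CT <- rep_len(CT, n); sigmaTheta <- rep_len(sigmaTheta, n)
  if (any(!is.finite(SA) | !is.finite(CT) | !is.finite(sigmaTheta)))
    stop("classifyWaterMass requires finite SA, CT and sigmaTheta")
  out <- rep("UNCLASSIFIED", n)
  cold <- CT <= 0
  out[cold & sigmaTheta <= 27.97] <- "POLAR"
  out[cold & sigmaTheta > 27.97 & CT > -1.1] <- "INTERMEDIATE"
  out[cold & sigmaTheta > 27.97 & CT <= -1.1] <- "CBSDW"
  out[!cold & SA < 35.06] <- "WARM_POLAR"
  out[!cold & SA >= 35.06 & CT > 2] <- "ATLANTIC"
  out[!cold & SA >= 35.06 & CT <= 2] <- "MODIFIED_ATLANTIC"
  factor(out, levels = waterMassLevels)
}

#' Inter-instrument calibration offsets from a stable layer
#'
#' Measures constant temperature and salinity offsets between a reference
#' profile (laboratory-calibrated instrument) and a target profile over a
#' depth window inside a stable water layer, as mean(reference - target).
#' The window must lie in a layer where the reference vertical temperature
#' gradient is small, otherwise small depth mismatches masquerade as
#' sensor offsets.
#'
#' @param reference,target \linkS4class{CtdProfile}s covering the window.
#' @param window depth range c(top, bottom), m.
#' @param maxGradient maximum tolerated mean |dTheta/dz| of the reference
#'   inside the window, deg C per m (default 0.02).
#' @return named vector \code{c(dT = , dS = )}: offsets to add to the
#'   target (see \code{\link{applyOffsets}}).
#' @export
calibrateOffsets <- function(reference, target, window, maxGradient = 0.02) {
  w <- sort(window)
  for (p in list(reference, target))
    if (min(p@depth) > w[1] || max(p@depth) < w[2])
      stop("calibration window outside profile depth range")
  sel <- reference@depth >= w[1] & reference@depth <= w[2]
  if (sum(sel) < 2) stop("calibration window contains fewer than two samples")
  d <- reference@depth[sel]
  grad <- mean(abs(diff(reference@CT[sel]) / diff(d)))
  if (grad > maxGradient)
    stop(sprintf("unstable window: mean |dCT/dz| = %.4f exceeds %.4f deg C/m",
                 grad, maxGradient))
  tCT <- stats::approx(target@depth, target@CT, d)$y
  tSA <- stats::approx(target@depth, target@SA, d)$y
  c(dT = mean(reference@CT[sel] - tCT), dS = mean(reference@SA[sel] - tSA))
}

#' Apply calibration offsets to a profile
#'
#' Adds the offsets from \code{\link{calibrateOffsets}} to the target
#' profile's temperature and salinity and recomputes density with the
#' linearized equation of state.
#'
#' @param profile a \linkS4class{CtdProfile}.
#' @param offsets named vector with elements \code{dT} and \code{dS}.
#' @return the corrected \linkS4class{CtdProfile}.
#' @export
applyOffsets <- function(profile, offsets) {
  profile@CT <- profile@CT + offsets[["dT"]]
  profile@SA <- profile@SA + offsets[["dS"]]
  profile@sigmaTheta <- linearSigmaTheta(profile@CT, profile@SA)
  validObject(profile)
  profile
}

#' Brunt-Vaisala frequency squared from a density profile
#'
#' N2 at layer midpoints from adjacent density levels:
#' N2 = (g / rho0) * d(sigma-theta)/dz, with z positive down, so stable
#' stratification (density increasing with depth) gives N2 > 0.
#'
#' @param profile a \linkS4class{CtdProfile} with at least two levels.
#' @param g gravity, m s-2 (default 9.81).
#' @param rho0 reference density, kg m-3 (default 1025).
#' @return data.frame with columns \code{depth} (midpoints, m) and
#'   \code{n2} (s-2).
#' @export
bruntVaisala <- function(profile, g = 9.81, rho0 = 1025) {
  z <- profile@depth
  if (length(z) < 2) stop("at least two depth levels required")
  dz <- diff(z)
  if (any(dz == 0)) stop("duplicate depths in profile")
  data.frame(depth = z[-length(z)] + dz / 2,
             n2 = (g / rho0) * diff(profile@sigmaTheta) / dz)
}

## NA-propagating piecewise-linear interpolation: result is NA wherever a
## bounding node is NA, and outside the node range (no extrapolation).
.interp1NA <- function(x, y, xi) {
  n <- length(x)
  out <- rep(NA_real_, length(xi))
  i <- findInterval(xi, x)
  exact <- !is.na(i) & i >= 1 & i <= n & xi == x[pmax(i, 1)]
  out[exact] <- y[i[exact]]
  inb <- which(i >= 1 & i < n & !exact)
  if (length(inb)) {
    i0 <- i[inb]; w <- (xi[inb] - x[i0]) / (x[i0 + 1] - x[i0])
    out[inb] <- (1 - w) * y[i0] + w * y[i0 + 1]
  }
  out
}

#' Interpolate CTD profiles onto a latitude x depth section
#'
#' Bilinear interpolation: each profile is first interpolated onto the
#' common depth grid, then values are linearly interpolated between the
#' bracketing profiles at each latitude. Cells outside the profile hull
#' (beyond the outermost stations, or below the shallower of the two
#' bracketing profiles) are masked rather than extrapolated.
#'
#' @param profiles list of \linkS4class{CtdProfile}s at distinct latitudes.
#' @param latGrid,depthGrid strictly increasing output grids (deg N, m);
#'   defaults span the profiles at 0.01 deg and 1 m.
#' @return a \linkS4class{CtdSection}.
#' @export
interpolateSection <- function(profiles, latGrid = NULL, depthGrid = NULL) {
  lats <- vapply(profiles, function(p) p@latitude, numeric(1))
  if (length(unique(lats)) < 2)
    stop("at least two profiles at distinct latitudes required")
  o <- order(lats)
  profiles <- profiles[o]; lats <- lats[o]
  if (is.null(latGrid)) latGrid <- seq(min(lats), max(lats), by = 0.01)
  if (is.null(depthGrid)) {
    zmax <- max(vapply(profiles, function(p) max(p@depth), numeric(1)))
    depthGrid <- seq(0, zmax, by = 1)
  }
  onDepth <- function(field) vapply(profiles, function(p)
    .interp1NA(p@depth, slot(p, field), depthGrid), numeric(length(depthGrid)))
  interpLat <- function(m) { # m: depth x profiles -> lat x depth
    t(apply(m, 1, function(v) .interp1NA(lats, v, latGrid)))
  }
  CT <- t(interpLat(onDepth("CT")))
  SA <- t(interpLat(onDepth("SA")))
  ST <- t(interpLat(onDepth("sigmaTheta")))
  dim(CT) <- dim(SA) <- dim(ST) <- c(length(latGrid), length(depthGrid))
  mask <- is.na(CT) | is.na(SA) | is.na(ST)
  CT[mask] <- NA; SA[mask] <- NA; ST[mask] <- NA
  new("CtdSection", latitude = latGrid, depth = depthGrid,
      CT = CT, SA = SA, sigmaTheta = ST, mask = mask)
}

## shared maximum-|gradient| front locator on an irregular latitude series
.maxGradientFront <- function(lat, value, resolution, minGradient) {
  ok <- is.finite(lat) & is.finite(value)
  lat <- lat[ok]; value <- value[ok]
  if (length(lat) < 2) stop("need at least two latitudes with data")
  grid <- seq(min(lat), max(lat), by = resolution)
  v <- stats::approx(lat, value, grid, ties = mean)$y
  d <- abs(diff(v))
  if (!length(d)) return(NA_real_)
  if (max(d) / resolution < minGradient) return(NA_real_)
  i <- which.max(d) # which.max takes the first maximum: ties -> lowest latitude
  (grid[i] + grid[i + 1]) / 2
}

#' Locate the subsurface front from a CTD section
#'
#' Averages temperature over a depth band (default 45-55 m, below surface
#' mixing), linearly interpolates the band mean across the latitudinal
#' range at the given resolution (default 0.01 deg), and returns the
#' midpoint of the adjacent-grid-point interval with the largest absolute
#' temperature change. Ties break toward the lowest latitude. Returns NA
#' when no gradient reaches \code{minGradient} (no discernible front).
#'
#' @param section a \linkS4class{CtdSection} covering the band.
#' @param band depth band c(top, bottom), m; grid bin means inside the
#'   closed band are used.
#' @param resolution latitude grid step, deg (default 0.01).
#' @param minGradient minimum gradient to accept a front, deg C per deg
#'   latitude (default 0.5).
#' @return front latitude, deg N, or NA when absent.
#' @export
locateSubsurfaceFront <- function(section, band = c(45, 55),
                                  resolution = 0.01, minGradient = 0.5) {
  sel <- section@depth >= band[1] & section@depth <= band[2]
  if (!any(sel)) stop("section does not cover the depth band")
  sub <- section@CT[, sel, drop = FALSE]
  bandMean <- rowMeans(sub, na.rm = TRUE)
  bandMean[!is.finite(bandMean)] <- NA
  if (sum(is.finite(bandMean)) < 2)
    stop("depth band entirely masked")
  .maxGradientFront(section@latitude, bandMean, resolution, minGradient)
}

#' Locate the surface front from a sea-surface-temperature series
#'
#' Applies the same maximum-|gradient| rule as
#' \code{\link{locateSubsurfaceFront}} to a latitude -> SST series. Returns
#' NA when the largest gradient is below \code{minGradient}, the situation
#' of a season with continuously warm, weakly graded surface water where
#' no distinct surface thermal front exists.
#'
#' @param lat latitudes, deg N, strictly increasing.
#' @param sst sea-surface temperature, deg C.
#' @param resolution,minGradient as in \code{\link{locateSubsurfaceFront}}.
#' @return front latitude, deg N, or NA when absent.
#' @export
locateSurfaceFront <- function(lat, sst, resolution = 0.01, minGradient = 0.5) {
  if (length(lat) < 3) stop("at least three points required")
  if (any(diff(lat) <= 0)) stop("latitudes must be strictly increasing")
  .maxGradientFront(lat, sst, resolution, minGradient)
}

#' Signed distance from a point to a frontal feature latitude
#'
#' Haversine distance (Earth radius 6371 km) between the point and the
#' feature latitude at the point's longitude, positive when the point lies
#' north of the feature. Correlations against frontal distance need a
#' monotone covariate, hence the signed default; set \code{signed = FALSE}
#' for the unsigned distance.
#'
#' @param lat,lon point coordinates, decimal degrees.
#' @param featureLat feature latitude, deg N.
#' @param signed return signed distance (default TRUE).
#' @return distance in km (vectorized over points).
#' @export
distanceToFeature <- function(lat, lon, featureLat, signed = TRUE) {
  if (any(abs(c(lat, featureLat)) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  d <- geosphere::distHaversine(cbind(lon, lat), cbind(lon, featureLat),
                                r = 6371000) / 1000
  if (signed) d * sign(lat - featureLat) else d
}

#' Bin stratification into stability classes
#'
#' Optional binning of N2 values into ordered stability classes at
#' user-supplied thresholds. No default thresholds are claimed; they are
#' survey-specific configuration.
#'
#' @param n2 N2 values, s-2.
#' @param thresholds increasing class boundaries, s-2.
#' @param labels class labels, length \code{length(thresholds) + 1}.
#' @return factor of stability classes.
#' @export
stabilityClasses <- function(n2, thresholds,
                             labels = paste0("S", seq_along(thresholds) + 0:1)[
                               seq_len(length(thresholds) + 1)]) {
  if (any(diff(thresholds) <= 0)) stop("thresholds must be increasing")
  cut(n2, breaks = c(-Inf, thresholds, Inf), labels = labels, right = TRUE)
}
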