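## dB-differencing classification of integration cells and NASC echo
## integration into along-transect abundance series.

#' Classify integration cells by frequency response
#'
#' For cells whose top edge lies above \code{splitDepth} (default 150 m,
#' the 120 kHz observational range limit) and where both frequencies carry
#' a defined MVBS, the dB difference d = MVBS(120) - MVBS(38) drives the
#' classification: d <= \code{fishMax} (5 dB, the upper limit of signal
#' from fish) gives FISH; d > \code{zooMin} (over 10 dB) gives
#' MACROZOOPLANKTON; values in between stay UNCLASSIFIED. Cells below the
#' split are assumed to be fish wherever 38 kHz is defined. Cells with no
#' defined MVBS are EXCLUDED. Cells straddling the split are assigned by
#' their top edge.
#'
#' @param mvbs38,mvbs120 co-registered \linkS4class{MvbsGrid}s.
#' @param splitDepth multifrequency depth limit, m (default 150).
#' @param fishMax inclusive upper dB-difference limit for fish (default 5).
#' @param zooMin exclusive lower dB-difference limit for macrozooplankton
#'   (default 10).
#' @return a \linkS4class{ClassifiedGrid}.
#' @export
classifyCells <- function(mvbs38, mvbs120, splitDepth = 150, fishMax = 5,
                          zooMin = 10) {
  if (!isTRUE(all.equal(mvbs38@depthEdges, mvbs120@depthEdges)) ||
      !isTRUE(all.equal(mvbs38@distEdges, mvbs120@distEdges)))
    stop("mismatched grid geometry between 38 and 120 kHz")
  tops <- mvbs38@depthEdges[-length(mvbs38@depthEdges)]
  shallow <- tops < splitDepth
  m38 <- mvbs38@mvbs; m120 <- mvbs120@mvbs
  m120[, !shallow] <- NA # 120 kHz unusable below the split
  delta <- m120 - m38
  cls <- matrix("EXCLUDED", nrow(m38), ncol(m38))
  shal <- matrix(rep(shallow, each = nrow(m38)), nrow(m38))
  both <- shal & !is.na(delta)
  cls[both & delta <= fishMax] <- "FISH"
  cls[both & delta > zooMin] <- "MACROZOOPLANKTON"
  cls[both & delta > fishMax & delta <= zooMin] <- "UNCLASSIFIED"
  deepFish <- !shal & !is.na(m38)
  cls[deepFish] <- "FISH"
  new("ClassifiedGrid", depthEdges = mvbs38@depthEdges,
      distEdges = mvbs38@distEdges, delta = delta, cellClass = cls,
      stratum = ifelse(shallow, "SHALLOW", "DEEP"), mvbs38 = m38,
      mvbs120 = m120, splitDepth = splitDepth, latitude = mvbs38@latitude,
      longitude = mvbs38@longitude, date = mvbs38@date)
}

#' Integrate classified cells into a NASC abundance series
#'
#' Nautical area scattering coefficient per along-transect distance bin:
#' NASC = 4 pi 1852^2 * sum over selected cells of 10^(MVBS/10) * thickness
#' (m2 nmi-2). Fish NASC integrates the 38 kHz MVBS and macrozooplankton
#' NASC the 120 kHz MVBS by default. Columns of the classified grid are
#' apportioned to output bins by overlap length, so the distance-weighted
#' total sum(NASC * binWidth) is conserved under bin-size changes. Empty
#' selections yield 0, which is a valid observation, not an error.
#'
#' @param classified a \linkS4class{ClassifiedGrid}.
#' @param cellClass class to integrate: "FISH" or "MACROZOOPLANKTON".
#' @param stratum "SHALLOW" (top edge < split), "DEEP" or "ALL".
#' @param binWidth output distance bin, nmi (default 0.1; the integration
#'   grid itself is typically 0.25 nmi).
#' @param mvbsSource "auto" (38 kHz for fish, 120 kHz for zooplankton),
#'   "f38" or "f120".
#' @return data.frame: date, distance (bin centre, nmi), latitude,
#'   longitude, stratum, class, nasc (m2 nmi-2).
#' @export
integrateNasc <- function(classified, cellClass = "FISH",
                          stratum = c("ALL", "SHALLOW", "DEEP"),
                          binWidth = 0.1, mvbsSource = "auto") {
  stratum <- match.arg(stratum)
  src <- if (mvbsSource == "auto") {
    if (cellClass == "MACROZOOPLANKTON") "f120" else "f38"
  } else mvbsSource
  m <- if (src == "f120") classified@mvbs120 else classified@mvbs38
  sel <- classified@cellClass == cellClass
  if (stratum != "ALL")
    sel <- sel & matrix(rep(classified@stratum == stratum, each = nrow(sel)),
                        nrow(sel))
  thick <- diff(classified@depthEdges)
  lin <- .dbToLin(m)
  lin[!sel | is.na(lin)] <- 0
  colNasc <- 4 * pi * 1852^2 * as.vector(lin %*% thick)
  de <- classified@distEdges
  d0 <- de[1]; dEnd <- de[length(de)]
  nBins <- ceiling((dEnd - d0) / binWidth - 1e-9)
  binL <- d0 + (seq_len(nBins) - 1) * binWidth
  binR <- pmin(binL + binWidth, dEnd)
  nasc <- numeric(nBins)
  for (b in seq_len(nBins)) {
    ov <- pmax(0, pmin(binR[b], de[-1]) - pmax(binL[b], de[-length(de)]))
    nasc[b] <- sum(colNasc * ov) / (binR[b] - binL[b])
  }
  ctr <- (binL + binR) / 2
  colCtr <- (de[-1] + de[-length(de)]) / 2
  if (length(colCtr) > 1) {
    lat <- stats::approx(colCtr, classified@latitude, ctr, rule = 2, ties = mean)$y
    lon <- stats::approx(colCtr, classified@longitude, ctr, rule = 2, ties = mean)$y
  } else {
    lat <- rep(classified@latitude, length(ctr))
    lon <- rep(classified@longitude, length(ctr))
  }
  data.frame(date = classified@date, distance = ctr, latitude = lat,
             longitude = lon, stratum = stratum, class = cellClass,
             nasc = nasc)
}

#' Cells fully inside a planted target's extent
#'
#' Maps a simulated target's along-transect and depth extent onto the
#' cells of a classified (or MVBS) grid: TRUE for cells lying entirely
#' inside the target rectangle. Used to score classification recovery
#' against planted ground truth.
#'
#' @param grid a \linkS4class{ClassifiedGrid} or \linkS4class{MvbsGrid}.
#' @param target a target list from \code{\link{fishSchool}} or
#'   \code{\link{zooplanktonLayer}}.
#' @return logical distance x depth matrix.
#' @export
targetCellMask <- function(grid, target) {
  de <- grid@distEdges; ze <- grid@depthEdges
  inD <- de[-length(de)] >= target$dist[1] & de[-1] <= target$dist[2]
  inZ <- ze[-length(ze)] >= target$depth[1] & ze[-1] <= target$depth[2]
  outer(inD, inZ, `&`)
}

#' Join frontal and hydrographic covariates onto a NASC series
#'
#' Adds, per distance bin: signed distances (km) to the daily surface
#' front, subsurface front and the open/closed ice edges (matched by
#' date; bins whose date has no front fix are dropped with a message),
#' plus temperature and salinity band means from the CTD section at the
#' bin latitude for the configured surface/middle/bottom depth bands.
#'
#' @param series NASC data.frame from \code{\link{integrateNasc}}.
#' @param fronts FrontFix data.frame: date, surface_front_lat,
#'   subsurface_front_lat, open_ice_lat, closed_ice_lat (NA = absent).
#' @param section a \linkS4class{CtdSection}.
#' @param bands named list of depth bands, m (defaults: surface 0-10,
#'   middle 45-55, bottom 150-250).
#' @return the series with covariate columns appended.
#' @export
joinCovariates <- function(series, fronts, section,
                           bands = list(surface = c(0, 10),
                                        middle = c(45, 55),
                                        bottom = c(150, 250))) {
  idx <- match(series$date, fronts$date)
  drop <- is.na(idx)
  if (any(drop))
    message(sprintf("dropping %d bin(s) without a daily front fix", sum(drop)))
  series <- series[!drop, , drop = FALSE]
  idx <- idx[!drop]
  fx <- fronts[idx, , drop = FALSE]
  feat <- c(surface_front = "surface_front_lat",
            deep_front = "subsurface_front_lat",
            open_ice = "open_ice_lat", closed_ice = "closed_ice_lat")
  for (nm in names(feat)) {
    fl <- fx[[feat[[nm]]]]
    series[[paste0("dist_", nm, "_km")]] <-
      ifelse(is.na(fl), NA_real_,
             distanceToFeature(series$latitude, series$longitude, fl))
  }
  bandMean <- function(field, band) {
    selz <- section@depth >= band[1] & section@depth <= band[2]
    v <- rowMeans(slot(section, field)[, selz, drop = FALSE], na.rm = TRUE)
    v[!is.finite(v)] <- NA
    stats::approx(section@latitude, v, series$latitude, rule = 2, ties = mean)$y
  }
  for (bn in names(bands)) {
    series[[paste0("temp_", bn)]] <- bandMean("CT", bands[[bn]])
    series[[paste0("sal_", bn)]] <- bandMean("SA", bands[[bn]])
  }
  series
}
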